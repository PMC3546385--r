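#' Construct a validated pedigree
#'
#' A pedigree is a tibble of individuals with parent links forming a
#' directed acyclic graph. Founders are individuals with both parents
#' unknown and are assumed mutually unrelated and non-inbred (the
#' conservative convention used for matriline founders in long-term field
#' studies).
#'
#' @param individuals A data frame with columns `id`, `sex` (`"F"` or
#'   `"M"`), and optionally `birth_year`, `death_year`, `mother_id`,
#'   `father_id`, `matriline_id`. Missing optional columns are created as
#'   `NA`. Empty strings in parent columns are treated as unknown.
#' @return A tibble of class `rut_pedigree` with a parent-first ordering
#'   stored in `attr(, "topo_order")`.
#' @examples
#' ped <- pedigree(tibble::tibble(
#'   id = c("F1", "M1", "C1"), sex = c("F", "M", "F"),
#'   mother_id = c(NA, NA, "F1"), father_id = c(NA, NA, "M1")
#' ))
#' kinship_matrix(ped)["F1", "C1"]
#' @export
pedigree <- function(individuals) {
  ind <- tibble::as_tibble(individuals)
  if (!all(c("id", "sex") %in% names(ind))) {
    stop("`individuals` must have at least `id` and `sex` columns",
         call. = FALSE)
  }
  for (col in c("birth_year", "death_year")) {
    if (!col %in% names(ind)) ind[[col]] <- NA_integer_
  }
  for (col in c("mother_id", "father_id", "matriline_id")) {
    if (!col %in% names(ind)) ind[[col]] <- NA_character_
    ind[[col]] <- as.character(ind[[col]])
    ind[[col]][!is.na(ind[[col]]) & ind[[col]] == ""] <- NA_character_
  }
  ind$id <- as.character(ind$id)
  ind$sex <- toupper(as.character(ind$sex))
  ind$sex <- ifelse(ind$sex %in% c("F", "FEMALE"), "F",
                    ifelse(ind$sex %in% c("M", "MALE"), "M", NA_character_))
  if (anyNA(ind$sex)) stop("`sex` must be female/F or male/M", call. = FALSE)
  if (anyDuplicated(ind$id)) stop("duplicate individual ids", call. = FALSE)

  mo <- match(ind$mother_id, ind$id)
  fa <- match(ind$father_id, ind$id)
  if (any(!is.na(ind$mother_id) & is.na(mo))) {
    stop("mother_id refers to an id not in the pedigree", call. = FALSE)
  }
  if (any(!is.na(ind$father_id) & is.na(fa))) {
    stop("father_id refers to an id not in the pedigree", call. = FALSE)
  }
  if (any(ind$sex[mo[!is.na(mo)]] != "F")) {
    stop("a mother_id refers to a male", call. = FALSE)
  }
  if (any(ind$sex[fa[!is.na(fa)]] != "M")) {
    stop("a father_id refers to a female", call. = FALSE)
  }
  both <- !is.na(ind$birth_year)
  for (p in list(mo, fa)) {
    ok <- both & !is.na(p) & !is.na(ind$birth_year[p])
    if (any(ind$birth_year[p[ok]] >= ind$birth_year[ok])) {
      stop("a parent is not older than its offspring", call. = FALSE)
    }
  }

  ord <- topo_order(fa, mo, ind$birth_year, ind$id)
  structure(ind, topo_order = ord,
            class = c("rut_pedigree", class(ind)))
}

# Parent-first ordering: generation depth, ties broken by birth year then
# id for determinism. Errors on parent-link cycles.
topo_order <- function(fa, mo, birth_year, id) {
  n <- length(id)
  depth <- rep(NA_real_, n)
  # depth of a parent slot: -1 for an unknown parent, NA while the known
  # parent is itself unresolved
  slot_depth <- function(p) {
    d <- rep(-1, n)
    known <- !is.na(p)
    d[known] <- depth[p[known]]
    d
  }
  repeat {
    dfa <- slot_depth(fa)
    dmo <- slot_depth(mo)
    ready <- is.na(depth) & !is.na(dfa) & !is.na(dmo)
    if (!any(ready)) break
    depth[ready] <- 1 + pmax(dfa[ready], dmo[ready])
  }
  if (anyNA(depth)) stop("cycle in pedigree parent links", call. = FALSE)
  by <- if (all(is.na(birth_year))) rep(0L, n) else birth_year
  order(depth, by, id, na.last = TRUE)
}

as_pedigree <- function(x) {
  if (inherits(x, "rut_pedigree")) x else pedigree(x)
}

parent_index <- function(ped) {
  ord <- attr(ped, "topo_order")
  ids <- ped$id[ord]
  list(
    ids = ids,
    father = match(ped$father_id[ord], ids) - 1L,
    mother = match(ped$mother_id[ord], ids) - 1L,
    unsort = match(ped$id, ids)
  )
}

#' Kinship matrix of a pedigree
#'
#' Computes the kinship coefficient K(i, j) — the probability that two
#' alleles sampled one from each individual are identical by descent —
#' for every pair, by the tabular method: K(i, i) = 0.5 (1 + K(father_i,
#' mother_i)) and K(i, j) = 0.5 (K(father_i, j) + K(mother_i, j)) with i
#' the later-born of the pair; unknown parents contribute zero and
#' founders are unrelated and non-inbred.
#'
#' @param ped A [pedigree()] (or a data frame coercible to one).
#' @return A symmetric numeric matrix with ids as dimnames, rows/columns
#'   in the input order.
#' @seealso [relatedness()], [inbreeding()]
#' @export
kinship_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  px <- parent_index(ped)
  K <- kinship_cpp(px$father, px$mother)
  dimnames(K) <- list(px$ids, px$ids)
  K[ped$id, ped$id, drop = FALSE]
}

#' Additive relatedness between two individuals
#'
#' The additive (numerator) relationship r = 2 K(i, j): 0.5 for
#' parent-offspring or full sibs, 0.25 for half sibs, 0.125 for an aunt
#' and her half-niece, and so on; relationship loops add.
#'
#' @param K A kinship matrix from [kinship_matrix()].
#' @param i,j Individual ids; must differ (for an individual with itself,
#'   use the inbreeding coefficient instead).
#' @return The relatedness coefficient as a single number.
#' @export
relatedness <- function(K, i, j) {
  if (identical(i, j)) {
    stop("relatedness is defined for two distinct individuals; ",
         "use inbreeding() for self terms", call. = FALSE)
  }
  if (!all(c(i, j) %in% rownames(K))) {
    stop("individual not present in kinship matrix", call. = FALSE)
  }
  2 * K[i, j]
}

#' Wright's inbreeding coefficients
#'
#' f of an individual equals the kinship of its parents; individuals with
#' any unknown parent (including founders) have f = 0.
#'
#' @inheritParams kinship_matrix
#' @return A tibble with columns `id` and `f`, one row per individual in
#'   input order.
#' @export
inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  px <- parent_index(ped)
  st <- kinship_stats_cpp(px$father, px$mother)
  tibble::tibble(id = ped$id, f = st$f[px$unsort])
}

#' Full-sibship sizes
#'
#' Partitions offspring with both parents known by (mother, father) pair.
#' Mean sibship size above one is the pedigree-level signature of pairs
#' re-mating across years in a singleton-litter species.
#'
#' @inheritParams kinship_matrix
#' @return A tibble with columns `mother_id`, `father_id`, `size`; the
#'   mean size is in `attr(, "mean_size")` (`NA` if there are no
#'   full sibships).
#' @export
sibship_sizes <- function(ped) {
  ped <- as_pedigree(ped)
  kids <- ped[!is.na(ped$mother_id) & !is.na(ped$father_id), ]
  out <- dplyr::count(kids, .data$mother_id, .data$father_id, name = "size")
  out <- tibble::as_tibble(out)
  attr(out, "mean_size") <- if (nrow(out)) mean(out$size) else NA_real_
  out
}

#' Matriline assignment
#'
#' Traces each individual's maternal line back to its terminal maternal
#' ancestor. If that ancestor is a founder female, she names the
#' matriline (offspring of either sex inherit their mother's matriline);
#' if the chain ends at a non-founder (unknown mother but known father)
#' the matriline is unknown.
#'
#' @inheritParams kinship_matrix
#' @return A tibble with columns `id` and `matriline` (`NA` where
#'   undefined).
#' @export
matrilines <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  mo <- match(ped$mother_id, ped$id)
  cur <- seq_len(n)
  for (step in seq_len(n + 1L)) {
    nxt <- ifelse(is.na(mo[cur]), cur, mo[cur])
    if (all(nxt == cur)) break
    if (step > n) stop("cycle in maternal links", call. = FALSE)
    cur <- nxt
  }
  term <- ped[cur, ]
  founder_female <- term$sex == "F" & is.na(term$mother_id) &
    is.na(term$father_id)
  tibble::tibble(
    id = ped$id,
    matriline = ifelse(founder_female, term$id, NA_character_)
  )
}

#' @rdname matrilines
#' @param id An individual id.
#' @return `matriline_of()` returns the single matriline token (or `NA`).
#' @export
matriline_of <- function(ped, id) {
  ml <- matrilines(ped)
  if (!id %in% ml$id) stop("unknown individual id", call. = FALSE)
  ml$matriline[ml$id == id]
}
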