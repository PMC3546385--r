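#' Lifetime mean rutting locations of males
#'
#' Arithmetic mean of easting and northing over every harem-holding
#' census record of each male, across all years. Males never censused
#' holding a harem are omitted (their count is in
#' `attr(, "n_omitted")`).
#'
#' @param census Census tibble.
#' @param ped Optional [pedigree()]; when supplied, only records of
#'   males in the pedigree are used and the omitted count refers to
#'   pedigree males.
#' @return A tibble: `male_id`, `mean_easting`, `mean_northing`,
#'   `n_records`.
#' @export
male_rut_locations <- function(census, ped = NULL) {
  harem <- census[census$harem_holder, ]
  if (!is.null(ped)) {
    ped <- as_pedigree(ped)
    males <- ped$id[ped$sex == "M"]
    harem <- harem[harem$individual_id %in% males, ]
  }
  out <- harem |>
    dplyr::group_by(male_id = .data$individual_id) |>
    dplyr::summarise(
      mean_easting = mean(.data$easting),
      mean_northing = mean(.data$northing),
      n_records = dplyr::n()
    ) |>
    dplyr::arrange(.data$male_id)
  out <- tibble::as_tibble(out)
  if (!is.null(ped)) {
    attr(out, "n_omitted") <- length(setdiff(ped$id[ped$sex == "M"],
                                             out$male_id))
  }
  out
}

#' Pairwise relatedness and rut-site distance for males
#'
#' One record per unordered pair of located males: additive relatedness
#' 2 K and Euclidean distance in metres between lifetime mean rut
#' locations.
#'
#' @param K Kinship matrix from [kinship_matrix()] covering all located
#'   males.
#' @param locations Output of [male_rut_locations()].
#' @return A tibble: `male1`, `male2`, `relatedness`, `distance`.
#' @export
male_pairwise_table <- function(K, locations) {
  loc <- locations[locations$male_id %in% rownames(K), ]
  n <- nrow(loc)
  if (n < 2) stop("need at least two located males", call. = FALSE)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(
    male1 = loc$male_id[idx[, 1]],
    male2 = loc$male_id[idx[, 2]],
    relatedness = 2 * K[cbind(match(loc$male_id[idx[, 1]], rownames(K)),
                              match(loc$male_id[idx[, 2]], colnames(K)))],
    distance = sqrt(
      (loc$mean_easting[idx[, 1]] - loc$mean_easting[idx[, 2]])^2 +
        (loc$mean_northing[idx[, 1]] - loc$mean_northing[idx[, 2]])^2
    )
  )
}

# Removes a grand mean and additive per-male effects from a pairwise
# response by damped iterative centering over the two identity margins.
# Returns the centred residuals; effects in attr(, "male_effects").
center_male_effects <- function(male1, male2, y, tol = 1e-10,
                                max_iter = 500L) {
  males <- sort(unique(c(male1, male2)))
  nm <- length(males)
  i1 <- match(male1, males)
  i2 <- match(male2, males)
  cnt <- tabulate(i1, nbins = nm) + tabulate(i2, nbins = nm)
  a <- numeric(nm)
  r <- y - mean(y)
  for (it in seq_len(max_iter)) {
    sums <- numeric(nm)
    agg <- rowsum(c(r, r), c(i1, i2))
    sums[as.integer(rownames(agg))] <- agg[, 1]
    delta <- 0.5 * sums / cnt
    r <- r - delta[i1] - delta[i2]
    r <- r - mean(r)
    a <- a + delta
    if (max(abs(delta)) < tol) break
  }
  attr(r, "male_effects") <- setNames(a, males)
  r
}

#' Relatedness-distance regression with a permutation null
#'
#' Tests whether related males rut near one another. The point estimate
#' is the slope of pairwise relatedness on pairwise rut-site distance
#' after removing additive per-male effects from the relatedness (both
#' members of every pair contribute an identity effect, estimated by
#' damped iterative centering over the two identity margins — pairwise
#' records are not independent). Inference is purely permutational: the
#' set of mean rut locations is randomly reassigned among the males,
#' distances and the slope recomputed, and the p value is the
#' tail frequency of permuted slopes at least as extreme as the
#' observed one, with the +1 correction
#' p = (1 + n_extreme) / (1 + n_permutations).
#'
#' The default alternative is `"less"` — the a priori directional
#' hypothesis that related males rut *near* one another (negative
#' slope). A fixed direction keeps the permutation test exact-level;
#' choosing the tail after seeing the slope's sign would double the
#' type-I error.
#'
#' @param pairs Output of [male_pairwise_table()].
#' @param n_permutations Number of location permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param alternative `"less"` (default), `"greater"`, or
#'   `"two.sided"`.
#' @return An object of class `spatial_fit`: slope (relatedness per
#'   metre), intercept, variance of the estimated per-male effects,
#'   permutation p value, pair and male counts, and the permuted slopes.
#' @export
fit_relatedness_distance <- function(pairs, n_permutations = 999L,
                                     seed = 1L,
                                     alternative = c("less", "greater",
                                                     "two.sided")) {
  alternative <- match.arg(alternative)
  males <- sort(unique(c(pairs$male1, pairs$male2)))
  nm <- length(males)
  if (nm < 3) stop("need at least three males", call. = FALSE)
  if (stats::var(pairs$distance) == 0) {
    stop("all pairwise distances are equal; slope undefined",
         call. = FALSE)
  }
  rc <- center_male_effects(pairs$male1, pairs$male2, pairs$relatedness)
  d <- pairs$distance
  slope_of <- function(dd) {
    stats::cov(rc, dd) / stats::var(dd)
  }
  slope <- slope_of(d)
  intercept <- mean(pairs$relatedness) - slope * mean(d)

  # permuting whole location assignments among males = permuting the
  # rows/columns of the fixed location-distance matrix
  i1 <- match(pairs$male1, males)
  i2 <- match(pairs$male2, males)
  D0 <- matrix(0, nm, nm)
  D0[cbind(i1, i2)] <- d
  D0[cbind(i2, i1)] <- d
  set.seed(seed)
  perm_slopes <- vapply(seq_len(n_permutations), function(b) {
    p <- sample.int(nm)
    slope_of(D0[cbind(p[i1], p[i2])])
  }, numeric(1))
  n_extreme <- switch(alternative,
    less = sum(perm_slopes <= slope),
    greater = sum(perm_slopes >= slope),
    two.sided = sum(abs(perm_slopes) >= abs(slope))
  )
  structure(
    list(slope = slope, intercept = intercept,
         alternative = alternative,
         var_male_effects = stats::var(attr(rc, "male_effects")),
         p_permutation = (1 + n_extreme) / (1 + n_permutations),
         n_pairs = nrow(pairs), n_males = nm,
         n_permutations = as.integer(n_permutations), seed = seed,
         perm_slopes = perm_slopes, pairs = pairs),
    class = "spatial_fit"
  )
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat("Relatedness-distance permutation test\n")
  cat(sprintf("  slope: %.3g relatedness per metre (%d males, %d pairs)\n",
              x$slope, x$n_males, x$n_pairs))
  cat(sprintf("  permutation p: %.4g (%d permutations)\n",
              x$p_permutation, x$n_permutations))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spatial_fit <- function(x, ...) {
  tibble::tibble(
    term = c("distance", "(Intercept)"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @exportS3Method generics::glance
glance.spatial_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, p_permutation = x$p_permutation,
    var_male_effects = x$var_male_effects,
    n_pairs = x$n_pairs, n_males = x$n_males,
    n_permutations = x$n_permutations
  )
}
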