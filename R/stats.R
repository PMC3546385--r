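#' Mating-opportunity accounting for observed pairs
#'
#' For every distinct (dam, sire) pair in the pedigree, the years in
#' which they mated and the years in which they had the opportunity to
#' mate: a year counts as an opportunity when the dam conceived (calved
#' the following spring) and the male rutted within the study area (held
#' a harem at least once that year), plus all years in which the pair
#' actually mated. Pairs that mated in more than one year are the
#' re-mating events.
#'
#' @param ped A [pedigree()] with sire assignments.
#' @param calvings Calvings tibble.
#' @param census Census tibble.
#' @return A tibble with columns `female_id`, `male_id`, `mated_years`,
#'   `opportunity_years` (list-columns of integer years), `n_mated`,
#'   `n_opportunity`.
#' @export
pair_opportunities <- function(ped, calvings, census) {
  ped <- as_pedigree(ped)
  bad <- !is.na(ped$father_id) & is.na(ped$mother_id)
  if (any(bad)) {
    stop("calf with a sire but no dam: ",
         paste(head(ped$id[bad]), collapse = ", "), call. = FALSE)
  }
  win <- oestrus_windows(calvings)
  calves <- tibble::tibble(
    calf_id = ped$id, female_id = ped$mother_id, male_id = ped$father_id
  ) |>
    dplyr::filter(!is.na(.data$male_id), !is.na(.data$female_id)) |>
    dplyr::inner_join(dplyr::select(win, "calf_id", "rut_year"),
                      by = "calf_id")
  fem_years <- split(win$rut_year, win$female_id)
  male_years <- census |>
    dplyr::filter(.data$harem_holder) |>
    dplyr::distinct(.data$individual_id, .data$rut_year)
  male_years <- split(male_years$rut_year, male_years$individual_id)
  pairs <- calves |>
    dplyr::group_by(.data$female_id, .data$male_id) |>
    dplyr::summarise(mated_years = list(sort(unique(.data$rut_year))),
                     .groups = "drop")
  pairs$opportunity_years <- purrr::pmap(
    list(pairs$female_id, pairs$male_id, pairs$mated_years),
    function(f, m, mated) {
      joint <- intersect(fem_years[[f]],
                         if (is.null(male_years[[m]])) integer()
                         else male_years[[m]])
      sort(unique(c(mated, joint)))
    }
  )
  pairs$n_mated <- lengths(pairs$mated_years)
  pairs$n_opportunity <- lengths(pairs$opportunity_years)
  pairs
}

#' Re-mating percentages
#'
#' The percentage of pairs that mated in more than one year among pairs
#' with the opportunity to mate in more than one year, and the
#' percentage of females (males) involved in at least one re-mated pair
#' among females (males) involved in at least one multi-year-opportunity
#' pair.
#'
#' @param opportunities Output of [pair_opportunities()].
#' @return A one-row tibble: `pct_pairs_remating`,
#'   `pct_females_remating`, `pct_males_remating` (`NA` when a
#'   denominator is zero).
#' @export
remating_stats <- function(opportunities) {
  multi <- opportunities$n_opportunity >= 2
  remated <- opportunities$n_mated >= 2
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    pct_pairs_remating = pct(sum(remated), sum(multi)),
    pct_females_remating = pct(
      dplyr::n_distinct(opportunities$female_id[remated]),
      dplyr::n_distinct(opportunities$female_id[multi])
    ),
    pct_males_remating = pct(
      dplyr::n_distinct(opportunities$male_id[remated]),
      dplyr::n_distinct(opportunities$male_id[multi])
    )
  )
}

#' Female mate diversity ratio
#'
#' Per female: the number of different sires of her calves divided by
#' her number of calves (restricted to calves with a known sire);
#' unweighted mean over females with at least one such calf. Values
#' below one indicate repeated mating with the same male.
#'
#' @inheritParams pair_opportunities
#' @return A single numeric ratio (`NA` if no female qualifies).
#' @export
female_mate_diversity <- function(ped) {
  ped <- as_pedigree(ped)
  kids <- ped[!is.na(ped$mother_id) & !is.na(ped$father_id), ]
  if (!nrow(kids)) return(NA_real_)
  per <- kids |>
    dplyr::group_by(.data$mother_id) |>
    dplyr::summarise(ratio = dplyr::n_distinct(.data$father_id) / dplyr::n())
  mean(per$ratio)
}

#' Intralineage polygyny ratio
#'
#' Per male with at least one known mate: the number of distinct
#' matrilines among his mates divided by his number of distinct mates;
#' unweighted mean over males. One means the male never mated two
#' females of the same matriline; values below one indicate increasing
#' intralineage polygyny. Dams with unknown matriline each count as
#' their own singleton lineage (conservative, mirroring the founder
#' assumption).
#'
#' @inheritParams pair_opportunities
#' @param matriline_tbl Optional tibble (`id`, `matriline`), e.g. from
#'   [matrilines()]; computed from the pedigree when omitted.
#' @return A single numeric ratio (`NA` if no male has a known mate).
#' @export
intralineage_polygyny <- function(ped, matriline_tbl = NULL) {
  ped <- as_pedigree(ped)
  if (is.null(matriline_tbl)) matriline_tbl <- matrilines(ped)
  kids <- ped[!is.na(ped$mother_id) & !is.na(ped$father_id), ]
  if (!nrow(kids)) return(NA_real_)
  ml <- matriline_tbl$matriline[match(kids$mother_id, matriline_tbl$id)]
  ml <- ifelse(is.na(ml), paste0(".self.", kids$mother_id), ml)
  per <- tibble::tibble(male = kids$father_id, mate = kids$mother_id,
                        ml = ml) |>
    dplyr::distinct(.data$male, .data$mate, .data$ml) |>
    dplyr::group_by(.data$male) |>
    dplyr::summarise(ratio = dplyr::n_distinct(.data$ml) /
                       dplyr::n_distinct(.data$mate))
  mean(per$ratio)
}

#' Mean pairwise relatedness
#'
#' Mean additive relatedness 2 K(i, j) over all unordered distinct pairs
#' of pedigree members.
#'
#' @inheritParams pair_opportunities
#' @return A single numeric coefficient (`NA` for pedigrees with fewer
#'   than two individuals).
#' @export
mean_pairwise_relatedness <- function(ped) {
  ped <- as_pedigree(ped)
  if (nrow(ped) < 2) return(NA_real_)
  px <- parent_index(ped)
  kinship_stats_cpp(px$father, px$mother)$mean_relatedness
}

#' Inbreeding summary
#'
#' Mean inbreeding coefficient over all pedigree members (founders'
#' f = 0 included), the number of nonzero coefficients, and the number
#' of close inbreeding events (f >= 0.125).
#'
#' @inheritParams pair_opportunities
#' @return A one-row tibble: `mean_f`, `n_f_nonzero`, `n_f_close`.
#' @export
inbreeding_stats <- function(ped) {
  ped <- as_pedigree(ped)
  px <- parent_index(ped)
  st <- kinship_stats_cpp(px$father, px$mother)
  tibble::tibble(
    mean_f = st$mean_f,
    n_f_nonzero = st$n_f_nonzero,
    n_f_close = st$n_f_close
  )
}

#' Names of the ten pedigree statistics
#' @export
STAT_NAMES <- c(
  "pct_pairs_remating", "pct_females_remating", "pct_males_remating",
  "mean_full_sibship", "mate_diversity", "intralineage_ratio",
  "mean_relatedness", "mean_f", "n_f_nonzero", "n_f_close"
)

#' The ten pedigree statistics
#'
#' Assembles, through one code path used identically for observed and
#' simulated pedigrees, the ten summary statistics: the three re-mating
#' percentages, mean full-sibship size, the female mate-diversity ratio,
#' the intralineage-polygyny ratio, mean pairwise relatedness, and the
#' three inbreeding summaries.
#'
#' @inheritParams pair_opportunities
#' @inheritParams intralineage_polygyny
#' @return A one-row tibble with the columns in [STAT_NAMES].
#' @export
stat_block <- function(ped, calvings, census, matriline_tbl = NULL) {
  ped <- as_pedigree(ped)
  sib <- sibship_sizes(ped)
  dplyr::bind_cols(
    remating_stats(pair_opportunities(ped, calvings, census)),
    tibble::tibble(
      mean_full_sibship = attr(sib, "mean_size"),
      mate_diversity = female_mate_diversity(ped),
      intralineage_ratio = intralineage_polygyny(ped, matriline_tbl),
      mean_relatedness = mean_pairwise_relatedness(ped)
    ),
    inbreeding_stats(ped)
  )
}
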