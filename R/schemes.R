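#' Floor applied to sampling weights so every eligible male stays
#' drawable ("sampled with replacement" implies no zero-probability
#' candidates)
#' @keywords internal
WEIGHT_EPS <- 1e-6

SCHEME_NAMES <- c("RANDOM", "TEMPORAL", "SPATIAL_500", "SPATIAL_100",
                  "AGE_CORRECTED", "BS_CORRECTED")

#' Null mating schemes
#'
#' The six constrained random-mating null models: fully random
#' (`RANDOM`), temporally constrained to the dam's oestrus window
#' (`TEMPORAL`), additionally spatially constrained to 500 m or 100 m
#' (`SPATIAL_500`, `SPATIAL_100`), and the 100-m scheme with sampling
#' weighted by age-predicted (`AGE_CORRECTED`) or identity-predicted
#' (`BS_CORRECTED`) annual breeding success.
#'
#' @param name Scheme name; lowercase aliases `random`, `temporal`,
#'   `spatial500`, `spatial100`, `age`, `bs` are accepted.
#' @return A list of class `rut_scheme` with fields `name`, `radius_m`
#'   (`NA` when unconstrained) and `weighting` (`"uniform"`, `"age"` or
#'   `"lbs"`).
#' @export
scheme <- function(name) {
  alias <- c(random = "RANDOM", temporal = "TEMPORAL",
             spatial500 = "SPATIAL_500", spatial100 = "SPATIAL_100",
             age = "AGE_CORRECTED", bs = "BS_CORRECTED")
  nm <- toupper(name)
  if (tolower(name) %in% names(alias)) nm <- alias[[tolower(name)]]
  if (!nm %in% SCHEME_NAMES) {
    stop("unknown scheme: ", name, call. = FALSE)
  }
  radius <- switch(nm,
    SPATIAL_500 = 500,
    SPATIAL_100 = ,
    AGE_CORRECTED = ,
    BS_CORRECTED = 100,
    NA_real_
  )
  weighting <- switch(nm,
    AGE_CORRECTED = "age",
    BS_CORRECTED = "lbs",
    "uniform"
  )
  structure(list(name = nm, radius_m = radius, weighting = weighting),
            class = "rut_scheme")
}

as_scheme <- function(x) {
  if (inherits(x, "rut_scheme")) x else scheme(x)
}

#' Annual breeding success records for candidate males
#'
#' One record per male-year in which the male was a candidate (held a
#' harem): his age that year and his annual breeding success (ABS, the
#' number of calves he sired that were conceived that rut year). Years in
#' which a candidate sired nothing contribute ABS = 0, which is essential
#' for an unbiased age curve.
#'
#' @param ped A [pedigree()] with sire assignments and birth years.
#' @param calvings Calvings tibble.
#' @param census Census tibble.
#' @return A tibble with columns `male_id`, `rut_year`, `age`, `abs`.
#' @export
abs_records <- function(ped, calvings, census) {
  ped <- as_pedigree(ped)
  cand <- census |>
    dplyr::filter(.data$harem_holder) |>
    dplyr::distinct(male_id = .data$individual_id, .data$rut_year)
  sired <- tibble::tibble(
    calf_id = ped$id,
    male_id = ped$father_id
  ) |>
    dplyr::filter(!is.na(.data$male_id)) |>
    dplyr::inner_join(
      dplyr::select(oestrus_windows(calvings), "calf_id", "rut_year"),
      by = "calf_id"
    ) |>
    dplyr::count(.data$male_id, .data$rut_year, name = "abs")
  out <- cand |>
    dplyr::left_join(sired, by = c("male_id", "rut_year")) |>
    dplyr::mutate(abs = dplyr::coalesce(.data$abs, 0L)) |>
    dplyr::left_join(
      tibble::tibble(male_id = ped$id, birth_year = ped$birth_year),
      by = "male_id"
    ) |>
    dplyr::mutate(age = .data$rut_year - .data$birth_year) |>
    dplyr::select("male_id", "rut_year", "age", "abs") |>
    dplyr::arrange(.data$male_id, .data$rut_year)
  tibble::as_tibble(out)
}

#' Age-predicted sampling weights
#'
#' Least-squares fit of ABS on age and its square; a male's sampling
#' weight at a given age is the predicted ABS, floored at a small
#' positive constant so extreme ages never get zero or negative weight.
#'
#' @param abs_tbl Output of [abs_records()] (columns `age`, `abs`).
#' @param eps Weight floor (default `1e-6`).
#' @return An object of class `age_weight_fit`: the `lm` coefficients,
#'   the floor, and a `weight(age)` function.
#' @export
fit_age_weights <- function(abs_tbl, eps = WEIGHT_EPS) {
  if (length(unique(abs_tbl$age[!is.na(abs_tbl$age)])) < 3) {
    stop("need ABS records at >= 3 distinct ages", call. = FALSE)
  }
  fit <- lm(abs ~ age + I(age^2), data = abs_tbl)
  if (anyNA(coef(fit))) {
    stop("degenerate design in ABS ~ age + age^2 fit", call. = FALSE)
  }
  b <- coef(fit)
  weight <- function(age) {
    pmax(b[[1]] + b[[2]] * age + b[[3]] * age^2, eps)
  }
  structure(
    list(coefficients = b, eps = eps, weight = weight, fit = fit),
    class = "age_weight_fit"
  )
}

#' @exportS3Method generics::tidy
tidy.age_weight_fit <- function(x, ...) {
  tidy_lm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(tidy_lm),
    estimate = tidy_lm[, 1],
    std.error = tidy_lm[, 2],
    statistic = tidy_lm[, 3],
    p.value = tidy_lm[, 4]
  )
}

#' Identity-predicted (lifetime breeding success) sampling weights
#'
#' The fitted value of the linear model of ABS on male identity is the
#' male's mean ABS across his candidate years; that mean, floored at
#' `eps`, is his sampling weight in every year.
#'
#' @inheritParams fit_age_weights
#' @param candidate_males Optional character vector; candidates with no
#'   ABS record are assigned the floor weight with a warning.
#' @return A tibble with columns `male_id`, `weight`.
#' @export
fit_lbs_weights <- function(abs_tbl, candidate_males = NULL,
                            eps = WEIGHT_EPS) {
  w <- abs_tbl |>
    dplyr::group_by(.data$male_id) |>
    dplyr::summarise(weight = mean(.data$abs)) |>
    dplyr::mutate(weight = pmax(.data$weight, eps))
  if (!is.null(candidate_males)) {
    missing <- setdiff(candidate_males, w$male_id)
    if (length(missing)) {
      warning(length(missing), " candidate male(s) had no ABS record; ",
              "assigned floor weight", call. = FALSE)
      w <- dplyr::bind_rows(
        w, tibble::tibble(male_id = missing, weight = eps)
      )
    }
  }
  dplyr::arrange(tibble::as_tibble(w), .data$male_id)
}
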