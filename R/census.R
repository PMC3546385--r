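#' Gestation length used for conception backdating, in days
#' @keywords internal
GESTATION_DAYS <- 235L

#' Oestrus-window half-width, in days (an 11-day inclusive window)
#' @keywords internal
WINDOW_HALF_DAYS <- 5L

conception_year <- function(birth_date) {
  as.integer(format(birth_date - GESTATION_DAYS, "%Y"))
}

#' Oestrus windows from calf birth dates
#'
#' Backdates each birth by the 235-day gestation to an estimated
#' conception date and places an 11-day (inclusive) window symmetrically
#' around it. The window is the temporal constraint used by the
#' constrained null mating schemes.
#'
#' @param calvings A tibble with columns `female_id`, `calf_id`,
#'   `calf_birth_date` (Date).
#' @return A tibble with one row per calving: `female_id`, `calf_id`,
#'   `rut_year`, `conception_date`, `window_start`, `window_end`.
#' @examples
#' oestrus_windows(tibble::tibble(
#'   female_id = "F1", calf_id = "C1",
#'   calf_birth_date = as.Date("1996-06-01")
#' ))
#' @export
oestrus_windows <- function(calvings) {
  conception <- calvings$calf_birth_date - GESTATION_DAYS
  tibble::tibble(
    female_id = calvings$female_id,
    calf_id = calvings$calf_id,
    rut_year = as.integer(format(conception, "%Y")),
    conception_date = conception,
    window_start = conception - WINDOW_HALF_DAYS,
    window_end = conception + WINDOW_HALF_DAYS
  )
}

#' Annual candidate females and males
#'
#' For each rut year, candidate females are those that conceived (calved
#' the following spring) and candidate males are those seen holding a
#' harem in that year's census. A male never censused as a harem holder
#' in a year is not a candidate in that year.
#'
#' @param census Census tibble (`rut_year`, `date`, `individual_id`,
#'   `easting`, `northing`, `harem_holder`).
#' @param calvings Calvings tibble (see [oestrus_windows()]).
#' @return A tibble with columns `rut_year`, `candidate_females`,
#'   `candidate_males` (list-columns of id vectors).
#' @export
candidate_table <- function(census, calvings) {
  win <- oestrus_windows(calvings)
  fem <- win |>
    dplyr::distinct(.data$rut_year, id = .data$female_id) |>
    dplyr::group_by(.data$rut_year) |>
    dplyr::summarise(candidate_females = list(sort(.data$id)))
  mal <- census |>
    dplyr::filter(.data$harem_holder) |>
    dplyr::distinct(.data$rut_year, id = .data$individual_id) |>
    dplyr::group_by(.data$rut_year) |>
    dplyr::summarise(candidate_males = list(sort(.data$id)))
  out <- dplyr::full_join(fem, mal, by = "rut_year") |>
    dplyr::arrange(.data$rut_year)
  out$candidate_females <- lapply(out$candidate_females,
                                  function(x) if (is.null(x)) character() else x)
  out$candidate_males <- lapply(out$candidate_males,
                                function(x) if (is.null(x)) character() else x)
  out
}

# The dam's location during her window: her own census record nearest in
# date to the estimated conception date, restricted to the window. NA
# coordinates if she has no record inside the window.
female_window_location <- function(census, window_row) {
  rec <- census[census$individual_id == window_row$female_id &
                  census$date >= window_row$window_start &
                  census$date <= window_row$window_end, ]
  if (!nrow(rec)) {
    return(c(easting = NA_real_, northing = NA_real_))
  }
  k <- which.min(abs(as.numeric(rec$date - window_row$conception_date)))
  c(easting = rec$easting[k], northing = rec$northing[k])
}

#' Eligible males for one female-year under a null mating scheme
#'
#' Applies the scheme's constraints in sequence: `RANDOM` admits every
#' candidate male of the year; `TEMPORAL` restricts to males with at
#' least one harem-holding census record inside the dam's 11-day oestrus
#' window; `SPATIAL_500` / `SPATIAL_100` further restrict to males with
#' such a record within 500 m / 100 m (inclusive, Euclidean) of the dam's
#' location on the conception date (her nearest censused date within the
#' window if the conception date itself was not censused).
#' `AGE_CORRECTED` and `BS_CORRECTED` share the `SPATIAL_100` eligible
#' set; their weighting applies at sampling time, not to eligibility.
#'
#' @param female_id Dam id.
#' @param rut_year Conception year.
#' @param scheme A [scheme()] or scheme name.
#' @param census Census tibble.
#' @param windows Output of [oestrus_windows()].
#' @param candidates Output of [candidate_table()] (computed if omitted).
#' @param calvings Needed only when `candidates` is omitted.
#' @return Character vector of eligible male ids (possibly empty; no
#'   fallback widening is applied here — see [simulate_pedigree()]).
#' @export
eligible_males <- function(female_id, rut_year, scheme, census, windows,
                           candidates = NULL, calvings = NULL) {
  sch <- as_scheme(scheme)
  if (is.null(candidates)) {
    if (is.null(calvings)) stop("supply `candidates` or `calvings`",
                                call. = FALSE)
    candidates <- candidate_table(census, calvings)
  }
  row <- which(candidates$rut_year == rut_year)
  cand <- if (length(row)) candidates$candidate_males[[row]] else character()
  if (sch$name == "RANDOM" || !length(cand)) {
    return(cand)
  }
  win <- windows[windows$female_id == female_id &
                   windows$rut_year == rut_year, ]
  if (!nrow(win)) {
    stop("female ", female_id, " has no oestrus window in ", rut_year,
         call. = FALSE)
  }
  win <- win[1, ]
  cen <- census[census$harem_holder &
                  census$date >= win$window_start &
                  census$date <= win$window_end &
                  census$individual_id %in% cand, ]
  if (is.na(sch$radius_m)) {
    return(sort(unique(cen$individual_id)))
  }
  loc <- female_window_location(census, win)
  if (is.na(loc[["easting"]])) {
    return(character())
  }
  d <- sqrt((cen$easting - loc[["easting"]])^2 +
              (cen$northing - loc[["northing"]])^2)
  sort(unique(cen$individual_id[d <= sch$radius_m]))
}
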