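#' Read and write study tables
#'
#' Delimited-text interchange for the four study tables. Empty fields are
#' unknown; dates are ISO-8601. `read_individuals()` returns a validated
#' [pedigree()]; `read_calvings()` derives the conception (rut) year by
#' backdating each birth by the 235-day gestation.
#'
#' @param path Path to a CSV file.
#' @return A tibble (a `rut_pedigree` for individuals).
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_individuals <- function(path) {
  ind <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    sex = readr::col_character(),
    birth_year = readr::col_integer(),
    death_year = readr::col_integer(),
    mother_id = readr::col_character(),
    father_id = readr::col_character(),
    matriline_id = readr::col_character()
  ))
  pedigree(ind)
}

#' @rdname study_io
#' @param ped A [pedigree()].
#' @export
write_individuals <- function(ped, path) {
  cols <- c("id", "sex", "birth_year", "death_year",
            "mother_id", "father_id", "matriline_id")
  readr::write_csv(as.data.frame(ped)[, cols], path, na = "")
  invisible(path)
}

#' @rdname study_io
#' @export
read_census <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    rut_year = readr::col_integer(),
    date = readr::col_date(),
    individual_id = readr::col_character(),
    easting = readr::col_double(),
    northing = readr::col_double(),
    harem_holder = readr::col_logical()
  ))
}

#' @rdname study_io
#' @param census A census tibble.
#' @export
write_census <- function(census, path) {
  readr::write_csv(census, path, na = "")
  invisible(path)
}

#' @rdname study_io
#' @export
read_calvings <- function(path) {
  cal <- readr::read_csv(path, col_types = readr::cols(
    female_id = readr::col_character(),
    calf_id = readr::col_character(),
    calf_birth_date = readr::col_date()
  ))
  cal$rut_year <- conception_year(cal$calf_birth_date)
  cal
}

#' @rdname study_io
#' @param calvings A calvings tibble.
#' @export
write_calvings <- function(calvings, path) {
  cols <- c("female_id", "calf_id", "calf_birth_date")
  readr::write_csv(as.data.frame(calvings)[, cols], path, na = "")
  invisible(path)
}
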