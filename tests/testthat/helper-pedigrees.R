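# Worked pedigree examples and random-pedigree generators shared across
# test files.

# Aunt and half-niece who also share a father: G is the shared
# grandmother, her daughters AUNT (by sire D) and MUM (by sire S2) are
# half-sisters, and NIECE is MUM's daughter by the same sire D. AUNT2 is
# an aunt by a different sire (pure aunt-half-niece, r = 0.125).
aunt_halfniece_pedigree <- function() {
  pedigree(tibble::tibble(
    id = c("G", "S1", "S2", "D", "AUNT", "MUM", "NIECE", "AUNT2"),
    sex = c("F", "M", "M", "M", "F", "F", "F", "F"),
    birth_year = c(1, 1, 1, 1, 2, 2, 3, 2),
    mother_id = c(NA, NA, NA, NA, "G", "G", "MUM", "G"),
    father_id = c(NA, NA, NA, NA, "D", "S2", "D", "S1")
  ))
}

# Parents QF (aunt) and PM (half-nephew) joined by three loops:
# shared grandmother G1 (aunt-half-nephew, 1/16), shared great-
# grandfather C2 (half first cousins once removed, 1/64), and shared
# great-great-grandmother C3 (half third cousins, 1/512). Their
# offspring X has f = 41/512 = 0.080078125.
three_loop_pedigree <- function() {
  pedigree(tibble::tibble(
    id = c("C3", "U0", "U1", "H1m", "F2", "V1", "C2", "W1",
           "J1", "W2", "J1m", "H1", "D2", "F1", "G1", "FP",
           "MUM", "QF", "PM", "X"),
    sex = c("F", "M", "M", "M", "M", "M", "M", "F",
            "F", "F", "M", "F", "F", "M", "F", "M",
            "F", "F", "M", "F"),
    birth_year = c(1, 1, 1, 1, 1, 1, 1, 1,
                   2, 2, 1, 3, 3, 3, 4, 4,
                   5, 5, 6, 7),
    mother_id = c(NA, NA, NA, NA, NA, NA, NA, NA,
                  "C3", "C3", NA, "J1", "W2", "W1", "H1", "D2",
                  "G1", "G1", "MUM", "QF"),
    father_id = c(NA, NA, NA, NA, NA, NA, NA, NA,
                  "U0", "U1", NA, "J1m", "C2", "C2", "H1m", "V1",
                  "F2", "F1", "FP", "PM")
  ))
}

# Random valid pedigree: founders first, then individuals whose parents
# are drawn (possibly unknown) from earlier generations.
random_pedigree <- function(n = 20, n_founders = 6, seed = 1,
                            p_orphan = 0.15) {
  set.seed(seed)
  id <- sprintf("i%02d", seq_len(n))
  sex <- c("F", "M", sample(c("F", "M"), n - 2, replace = TRUE))
  mother <- father <- rep(NA_character_, n)
  for (k in seq(n_founders + 1, n)) {
    fem <- which(sex[seq_len(k - 1)] == "F")
    mal <- which(sex[seq_len(k - 1)] == "M")
    if (length(fem) && runif(1) > p_orphan) {
      mother[k] <- id[fem[sample.int(length(fem), 1)]]
    }
    if (length(mal) && runif(1) > p_orphan) {
      father[k] <- id[mal[sample.int(length(mal), 1)]]
    }
  }
  pedigree(tibble::tibble(
    id = id, sex = sex, birth_year = seq_len(n),
    mother_id = mother, father_id = father
  ))
}

# Small synthetic study reused across test files (generated once).
tiny_config <- function(...) {
  base <- list(n_years = 10L, n_founder_females = 18L,
               n_founder_males = 9L, n_immigrant_males = 1L,
               grid_cells = c(18L, 12L))
  do.call(generator_config, utils::modifyList(base, list(...)))
}

tiny_study_cache <- new.env(parent = emptyenv())
tiny_study <- function() {
  if (is.null(tiny_study_cache$st)) {
    tiny_study_cache$st <- generate_study(tiny_config(), seed = 101)
  }
  tiny_study_cache$st
}

# Hand-built micro study: two rut years, two dams, three males with
# fully controlled census dates and locations.
micro_study <- function() {
  ped <- pedigree(tibble::tibble(
    id = c("DAM1", "DAM2", "MA", "MB", "MC", "K1", "K2", "K3"),
    sex = c("F", "F", "M", "M", "M", "F", "M", "F"),
    birth_year = c(1990, 1990, 1989, 1989, 1989, 1996, 1996, 1997),
    mother_id = c(NA, NA, NA, NA, NA, "DAM1", "DAM2", "DAM1"),
    father_id = c(NA, NA, NA, NA, NA, "MA", "MB", "MA")
  ))
  calvings <- tibble::tibble(
    female_id = c("DAM1", "DAM2", "DAM1"),
    calf_id = c("K1", "K2", "K3"),
    calf_birth_date = as.Date(c("1996-06-01", "1996-06-05", "1997-06-03"))
  )
  calvings$rut_year <- c(1995L, 1995L, 1996L)
  # conceptions: K1 1995-10-10, K2 1995-10-14, K3 1996-10-11
  census <- tibble::tibble(
    rut_year = c(1995L, 1995L, 1995L, 1995L, 1995L,
                 1996L, 1996L, 1996L),
    date = as.Date(c("1995-10-09", "1995-10-09", "1995-10-09",
                     "1995-10-20", "1995-10-13",
                     "1996-10-11", "1996-10-11", "1996-10-11")),
    individual_id = c("MA", "MB", "DAM1", "MC", "DAM2",
                      "MA", "MB", "DAM1"),
    easting = c(1000, 1300, 1000, 1000, 1300, 1000, 1100, 1000),
    northing = c(2000, 2000, 2000, 2000, 2000, 2000, 2000, 2000),
    harem_holder = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
  list(ped = ped, calvings = calvings, census = census)
}
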