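#' Configuration for the synthetic-study generator
#'
#' Defaults emulate a multi-decade individual-based study of a
#' harem-breeding ungulate: philopatric matrilineal females on a 100-m
#' census grid, site-faithful harem-holding males with an age-peaked
#' annual breeding success curve, an autumn rut with a roughly two-week
#' oestrus peak, 235-day gestation, and tunable re-mating fidelity and
#' harem monopolisation.
#'
#' @param n_years Number of rut years simulated (default 36).
#' @param n_founder_females Founder females, one matriline each
#'   (default 85).
#' @param n_founder_males Founder males present at the start
#'   (default 30).
#' @param n_immigrant_males Males entering the rutting pool from outside
#'   the study area each year (default 2).
#' @param grid_cells Grid extent in 100-m cells, `c(east, north)`
#'   (default `c(40, 25)`).
#' @param start_year First rut year (default 1971).
#' @param calving_prob Named vector of annual conception probabilities
#'   by female age class: `age2`, `age3_4`, `prime` (5-12) and `old`
#'   (13+).
#' @param calf_survival First-year survival probability.
#' @param female_survival,male_survival Annual adult survival; each a
#'   vector `c(prime, old)` with senescence after ages 12 (females) and
#'   10 (males).
#' @param max_age Hard upper age limit.
#' @param min_rut_age,max_rut_age Ages between which a male ruts in the
#'   study area (defaults 5 and 14; males rarely breed before 5).
#' @param abs_peak_age,abs_max,abs_floor Quadratic ABS-age curve
#'   `max(abs_max - (age - abs_peak_age)^2, abs_floor)`, peaking at 8-10
#'   years.
#' @param male_site_sd SD (m) of a male's annual rut site around his
#'   home rut site; small values make rut location highly repeatable.
#' @param male_philopatry Probability that a male's home rut site is
#'   near his mother's range (natal-site philopatry), rather than a
#'   uniform random grid location.
#' @param natal_site_sd SD (m) of a philopatric male's home site around
#'   his mother's range centre.
#' @param male_anchor_sd SD (m) of a non-philopatric male's home rut
#'   site around a randomly chosen matriline range centre: harems are
#'   defended where hind groups feed, so male rut sites concentrate on
#'   female-occupied ground rather than uniformly over the grid.
#' @param matriline_sd SD (m) of a female's range centre around her
#'   matriline centre (matriline home-range dispersion).
#' @param herding Probability that a female's rut-season location is the
#'   site of the harem nearest her range centre (she has been herded
#'   into it) rather than her own range centre; drives how often the
#'   true sire ruts within 100 m of the dam.
#' @param herd_radius Maximum distance (m) over which a female is drawn
#'   into a harem; beyond it she stays on her own ground, so weak male
#'   site fidelity (large `male_site_sd`) erodes close-proximity mating.
#' @param oestrus_peak_doy Peak conception day of year (default 288,
#'   mid-October).
#' @param oestrus_sd Individual SD of conception date in days; about a
#'   two-week peak at the default 6.
#' @param oestrus_matriline_sd SD (days) of a matriline-by-year
#'   synchrony effect shared by females of one matriline.
#' @param tenure_mean,tenure_sd Mean and between-male SD (days) of rut
#'   tenure length.
#' @param tenure_start_sd Between-male SD (days) of the repeatable
#'   tenure start offset; within-male annual jitter is 2 days.
#' @param fidelity_phi Probability a female re-uses her previous sire
#'   when he ruts during her oestrus window (mate fidelity).
#' @param harem_kappa Exponent concentrating sire sampling weights on
#'   the locally dominant male; 0 removes breeding-success skew.
#' @param spatial_lambda Distance-decay scale (m) of sire choice,
#'   `exp(-d / spatial_lambda)`; tuned so that at the defaults roughly
#'   75\\% of sires rut within 500 m and 50\\% within 100 m of the dam on
#'   conception day.
#' @param sire_model `"behavioural"` (fidelity + local weighted choice)
#'   or a uniform null scheme name (`"RANDOM"`, `"TEMPORAL"`,
#'   `"SPATIAL_500"`, `"SPATIAL_100"`) under which the true sires are
#'   drawn exactly as the matching simulation scheme would draw them
#'   (used for null calibration).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_years = 36L,
                             n_founder_females = 85L,
                             n_founder_males = 30L,
                             n_immigrant_males = 2L,
                             grid_cells = c(40L, 25L),
                             start_year = 1971L,
                             calving_prob = c(age2 = 0.25, age3_4 = 0.4,
                                              prime = 0.5, old = 0.35),
                             calf_survival = 0.6,
                             female_survival = c(prime = 0.92, old = 0.75),
                             male_survival = c(prime = 0.88, old = 0.7),
                             max_age = 20L,
                             min_rut_age = 5L,
                             max_rut_age = 14L,
                             abs_peak_age = 9,
                             abs_max = 16,
                             abs_floor = 0.5,
                             male_site_sd = 100,
                             male_philopatry = 0.7,
                             natal_site_sd = 150,
                             male_anchor_sd = 150,
                             matriline_sd = 100,
                             herding = 0.78,
                             herd_radius = 500,
                             oestrus_peak_doy = 288L,
                             oestrus_sd = 6,
                             oestrus_matriline_sd = 2,
                             tenure_mean = 24,
                             tenure_sd = 4,
                             tenure_start_sd = 4,
                             fidelity_phi = 0.3,
                             harem_kappa = 1,
                             spatial_lambda = 140,
                             sire_model = "behavioural") {
  cfg <- as.list(environment())
  probs <- c(cfg$calving_prob, cfg$calf_survival, cfg$female_survival,
             cfg$male_survival, cfg$male_philopatry, cfg$fidelity_phi)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(cfg$sire_model, "behavioural")) {
    nm <- toupper(cfg$sire_model)
    if (!nm %in% c("RANDOM", "TEMPORAL", "SPATIAL_500", "SPATIAL_100")) {
      stop("sire_model must be 'behavioural' or a uniform scheme name",
           call. = FALSE)
    }
    cfg$sire_model <- nm
  }
  structure(cfg, class = "generator_config")
}

snap100 <- function(x) 100 * round(x / 100)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic mating study
#'
#' Simulates the population year by year under a [generator_config()]:
#' survival and births, seasonal (matriline-synchronised) oestrus dates,
#' philopatric female ranges, site-faithful male rut tenures with daily
#' harem-holding census records, and sire choice with tunable mate
#' fidelity and local male dominance. All four study tables plus a
#' per-conception truth log are returned; the same config and seed
#' reproduce the study exactly.
#'
#' @param config A [generator_config()].
#' @param seed Master seed.
#' @return A list of class `synthetic_study`: `individuals` (a
#'   [pedigree()]), `census`, `calvings`, `truth` (per conception:
#'   dam, calf, rut year, number of eligible males, chosen sire,
#'   whether the choice was a fidelity re-use), and `config`.
#' @export
generate_study <- function(config = generator_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  ext_e <- cfg$grid_cells[1] * 100
  ext_n <- cfg$grid_cells[2] * 100

  rand_site <- function(n) {
    cbind(e = snap100(runif(n, 0, ext_e)), n = snap100(runif(n, 0, ext_n)))
  }

  nf <- cfg$n_founder_females
  nm <- cfg$n_founder_males
  fsite <- rand_site(nf)
  # male rut sites anchor to hind ground: a random matriline centre
  anchor_site <- function(n) {
    j <- sample.int(nf, n, replace = TRUE)
    cbind(e = clamp(fsite[j, 1] + rnorm(n, 0, cfg$male_anchor_sd), 0, ext_e),
          n = clamp(fsite[j, 2] + rnorm(n, 0, cfg$male_anchor_sd), 0, ext_n))
  }
  msite <- anchor_site(nm)
  ind <- tibble::tibble(
    id = c(sprintf("F%03d", seq_len(nf)), sprintf("M%03d", seq_len(nm))),
    sex = c(rep("F", nf), rep("M", nm)),
    birth_year = c(cfg$start_year - sample(2:12, nf, replace = TRUE),
                   cfg$start_year - sample(1:9, nm, replace = TRUE)),
    death_year = NA_integer_,
    mother_id = NA_character_,
    father_id = NA_character_,
    matriline_id = c(sprintf("F%03d", seq_len(nf)), rep(NA, nm)),
    home_e = c(fsite[, 1], msite[, 1]),
    home_n = c(fsite[, 2], msite[, 2]),
    tenure_start_off = c(rep(NA_real_, nf), rnorm(nm, 0, cfg$tenure_start_sd)),
    tenure_len = c(rep(NA_real_, nf),
                   pmax(rnorm(nm, cfg$tenure_mean, cfg$tenure_sd), 8))
  )
  next_calf <- 1L
  next_imm <- 1L
  prev_sire <- character()   # named by female id
  census_l <- list()
  calv_l <- list()
  truth_l <- list()

  abs_w <- function(age) {
    pmax(cfg$abs_max - (age - cfg$abs_peak_age)^2, cfg$abs_floor)
  }

  for (y in seq.int(cfg$start_year,
                    cfg$start_year + cfg$n_years - 1L)) {
    alive <- is.na(ind$death_year)
    age <- y - ind$birth_year

    # immigrant males join the rutting pool
    n_imm <- cfg$n_immigrant_males
    if (n_imm > 0) {
      isite <- anchor_site(n_imm)
      imm <- tibble::tibble(
        id = sprintf("I%03d", seq(next_imm, length.out = n_imm)),
        sex = "M",
        birth_year = y - sample(cfg$min_rut_age:(cfg$min_rut_age + 3),
                                n_imm, replace = TRUE),
        death_year = NA_integer_,
        mother_id = NA_character_, father_id = NA_character_,
        matriline_id = NA_character_,
        home_e = isite[, 1], home_n = isite[, 2],
        tenure_start_off = rnorm(n_imm, 0, cfg$tenure_start_sd),
        tenure_len = pmax(rnorm(n_imm, cfg$tenure_mean, cfg$tenure_sd), 8)
      )
      next_imm <- next_imm + n_imm
      ind <- dplyr::bind_rows(ind, imm)
      alive <- c(alive, rep(TRUE, n_imm))
      age <- c(age, y - imm$birth_year)
    }

    # rutting males: tenure block of daily harem-holding records at the
    # annual rut site (home site plus fidelity noise, on the 100 m grid)
    rut <- which(alive & ind$sex == "M" &
                   age >= cfg$min_rut_age & age <= cfg$max_rut_age)
    if (!length(rut)) {
      stop("population ran out of rutting males in year ", y,
           " (seed ", seed, ")", call. = FALSE)
    }
    peak <- as.Date(paste0(y, "-01-01")) + (cfg$oestrus_peak_doy - 1)
    m_e <- clamp(snap100(ind$home_e[rut] +
                           rnorm(length(rut), 0, cfg$male_site_sd)), 0, ext_e)
    m_n <- clamp(snap100(ind$home_n[rut] +
                           rnorm(length(rut), 0, cfg$male_site_sd)), 0, ext_n)
    m_start <- peak - 12 + round(ind$tenure_start_off[rut] + rnorm(length(rut), 0, 2))
    m_len <- pmax(round(ind$tenure_len[rut] + rnorm(length(rut), 0, 2)), 5)
    m_end <- m_start + m_len - 1
    males_y <- tibble::tibble(
      id = ind$id[rut], age = age[rut], e = m_e, n = m_n,
      start = m_start, end = m_end
    )
    harem_y <- tibble::tibble(
      date = as.Date(unlist(Map(function(s, e) seq(s, e, by = 1),
                                m_start, m_end)), origin = "1970-01-01"),
      individual_id = rep(males_y$id, m_len),
      easting = rep(m_e, m_len),
      northing = rep(m_n, m_len)
    )

    # conceiving females with seasonal, matriline-synchronised oestrus
    fem <- which(alive & ind$sex == "F" & age >= 2 & age <= cfg$max_age)
    p_c <- ifelse(age[fem] == 2, cfg$calving_prob[["age2"]],
           ifelse(age[fem] <= 4, cfg$calving_prob[["age3_4"]],
           ifelse(age[fem] <= 12, cfg$calving_prob[["prime"]],
                  cfg$calving_prob[["old"]])))
    conceiving <- fem[runif(length(fem)) < p_c]
    mls <- unique(ind$matriline_id[conceiving])
    ml_eff <- setNames(rnorm(length(mls), 0, cfg$oestrus_matriline_sd), mls)
    f_ml <- ind$matriline_id[conceiving]
    conc_date <- peak + round(rnorm(length(conceiving), 0, cfg$oestrus_sd) +
                                ifelse(is.na(f_ml), 0, ml_eff[f_ml]))

    # female rut locations: her range centre, or — with probability
    # `herding`, and only if one is within `herd_radius` — the site of
    # the nearest harem she has been herded into
    f_e <- clamp(snap100(ind$home_e[conceiving]), 0, ext_e)
    f_n <- clamp(snap100(ind$home_n[conceiving]), 0, ext_n)
    if (length(conceiving)) {
      near_m <- max.col(-outer(f_e, m_e, "-")^2 - outer(f_n, m_n, "-")^2)
      d_near <- sqrt((f_e - m_e[near_m])^2 + (f_n - m_n[near_m])^2)
      herded <- runif(length(conceiving)) < cfg$herding &
        d_near <= cfg$herd_radius
      f_e[herded] <- m_e[near_m[herded]]
      f_n[herded] <- m_n[near_m[herded]]
    }
    fem_cen <- tibble::tibble(
      date = rep(conc_date, each = 3) + c(-3L, 0L, 3L),
      individual_id = rep(ind$id[conceiving], each = 3),
      easting = rep(f_e, each = 3),
      northing = rep(f_n, each = 3)
    )

    cand_y <- sort(males_y$id)

    # sire choice per conception
    n_c <- length(conceiving)
    sire <- character(n_c)
    n_elig <- integer(n_c)
    reuse <- logical(n_c)
    for (k in seq_len(n_c)) {
      ws <- conc_date[k] - WINDOW_HALF_DAYS
      we <- conc_date[k] + WINDOW_HALF_DAYS
      inwin <- males_y$start <= we & males_y$end >= ws
      fid <- ind$id[conceiving[k]]
      if (cfg$sire_model == "behavioural") {
        el <- which(inwin)
        if (!length(el)) el <- seq_len(nrow(males_y))
        n_elig[k] <- length(el)
        prev <- prev_sire[fid]
        if (!is.na(prev) && prev %in% males_y$id[el] &&
              runif(1) < cfg$fidelity_phi) {
          sire[k] <- prev
          reuse[k] <- TRUE
        } else {
          d <- sqrt((males_y$e[el] - f_e[k])^2 + (males_y$n[el] - f_n[k])^2)
          w <- abs_w(males_y$age[el])^cfg$harem_kappa *
            exp(-d / cfg$spatial_lambda)
          sire[k] <- if (length(el) == 1L) males_y$id[el] else {
            sample(males_y$id[el], 1L, prob = w)
          }
        }
      } else {
        frow <- list(window_start = ws, window_end = we,
                     conception_date = conc_date[k])
        frec <- fem_cen[fem_cen$individual_id == fid, ]
        set <- character()
        for (lev in widen_ladder(cfg$sire_model)) {
          set <- eligible_at_level(lev, frow, cand_y, harem_y, frec)
          if (length(set)) break
        }
        n_elig[k] <- length(set)
        sire[k] <- if (length(set) == 1L) set else sample(set, 1L)
      }
      prev_sire[fid] <- sire[k]
    }

    # calves born the following spring
    if (n_c > 0) {
      calf_id <- sprintf("C%05d", seq(next_calf, length.out = n_c))
      next_calf <- next_calf + n_c
      calf_sex <- ifelse(runif(n_c) < 0.5, "F", "M")
      philo <- runif(n_c) < cfg$male_philopatry
      away <- anchor_site(n_c)
      home_e <- ifelse(calf_sex == "F" | philo,
                       ind$home_e[conceiving] + rnorm(n_c, 0,
                         ifelse(calf_sex == "F", cfg$matriline_sd,
                                cfg$natal_site_sd)),
                       away[, 1])
      home_n <- ifelse(calf_sex == "F" | philo,
                       ind$home_n[conceiving] + rnorm(n_c, 0,
                         ifelse(calf_sex == "F", cfg$matriline_sd,
                                cfg$natal_site_sd)),
                       away[, 2])
      calves <- tibble::tibble(
        id = calf_id, sex = calf_sex,
        birth_year = as.integer(y) + 1L, death_year = NA_integer_,
        mother_id = ind$id[conceiving], father_id = sire,
        matriline_id = ind$matriline_id[conceiving],
        home_e = clamp(home_e, 0, ext_e),
        home_n = clamp(home_n, 0, ext_n),
        tenure_start_off = ifelse(calf_sex == "M",
                                  rnorm(n_c, 0, cfg$tenure_start_sd), NA),
        tenure_len = ifelse(calf_sex == "M",
                            pmax(rnorm(n_c, cfg$tenure_mean,
                                       cfg$tenure_sd), 8), NA)
      )
      calv_l[[as.character(y)]] <- tibble::tibble(
        female_id = ind$id[conceiving], calf_id = calf_id,
        calf_birth_date = conc_date + GESTATION_DAYS
      )
      truth_l[[as.character(y)]] <- tibble::tibble(
        rut_year = as.integer(y), female_id = ind$id[conceiving],
        calf_id = calf_id,
        conception_date = conc_date, n_eligible = n_elig,
        sire_id = sire, fidelity_reuse = reuse
      )
      ind <- dplyr::bind_rows(ind, calves)
    }
    census_l[[as.character(y)]] <- dplyr::bind_rows(
      dplyr::mutate(harem_y, harem_holder = TRUE),
      dplyr::mutate(fem_cen, harem_holder = FALSE)
    ) |>
      dplyr::mutate(rut_year = as.integer(y)) |>
      dplyr::select("rut_year", "date", "individual_id", "easting",
                    "northing", "harem_holder") |>
      dplyr::arrange(.data$date, .data$individual_id)

    # survival to the next rut year
    alive <- is.na(ind$death_year)
    age <- y - ind$birth_year
    p_surv <- rep(1, nrow(ind))
    ad <- alive & age >= 1
    p_surv[ad & ind$sex == "F"] <-
      ifelse(age[ad & ind$sex == "F"] <= 12,
             cfg$female_survival[["prime"]], cfg$female_survival[["old"]])
    p_surv[ad & ind$sex == "M"] <-
      ifelse(age[ad & ind$sex == "M"] <= 10,
             cfg$male_survival[["prime"]], cfg$male_survival[["old"]])
    p_surv[alive & age == 0] <- cfg$calf_survival
    p_surv[alive & age >= cfg$max_age] <- 0
    dies <- alive & (runif(nrow(ind)) >= p_surv)
    ind$death_year[dies] <- as.integer(y)

    if (sum(is.na(ind$death_year) & ind$sex == "F" &
              (y + 1 - ind$birth_year) >= 2) == 0) {
      stop("female population extinct in year ", y, " (seed ", seed, ")",
           call. = FALSE)
    }
  }

  calvings <- dplyr::bind_rows(calv_l)
  calvings$rut_year <- conception_year(calvings$calf_birth_date)
  individuals <- pedigree(
    ind[c("id", "sex", "birth_year", "death_year", "mother_id",
          "father_id", "matriline_id")]
  )
  structure(
    list(individuals = individuals,
         census = dplyr::bind_rows(census_l),
         calvings = calvings,
         truth = dplyr::bind_rows(truth_l),
         config = cfg, seed = seed),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic mating study:", nrow(x$individuals), "individuals,",
      nrow(x$calvings), "calvings,", nrow(x$census), "census records\n")
  cat("  years:", x$config$start_year, "-",
      x$config$start_year + x$config$n_years - 1L,
      " sire model:", x$config$sire_model, " seed:", x$seed, "\n")
  invisible(x)
}

#' Demographic and spatial summary of a synthetic study
#'
#' Reports the quantities used to calibrate the generator defaults:
#' breeding years and distinct mates per female, sire ages, and the
#' fraction of true sires rutting within 500 m / 100 m of the dam on the
#' conception day (nearest harem record inside the oestrus window).
#'
#' @param study A [generate_study()] result.
#' @return A one-row tibble.
#' @export
demographic_summary <- function(study) {
  ped <- study$individuals
  truth <- study$truth
  if (!nrow(truth)) {
    return(tibble::tibble(
      n_conceptions = 0L, n_females = 0L, n_sires = 0L,
      mean_breeding_years = NA_real_, mean_distinct_mates = NA_real_,
      mean_sire_age = NA_real_, prop_sire_500m = NA_real_,
      prop_sire_100m = NA_real_
    ))
  }
  per_f <- truth |>
    dplyr::group_by(.data$female_id) |>
    dplyr::summarise(years = dplyr::n_distinct(.data$rut_year),
                     mates = dplyr::n_distinct(.data$sire_id))
  birth <- setNames(ped$birth_year, ped$id)
  sire_age <- truth$rut_year - birth[truth$sire_id]

  harem <- study$census[study$census$harem_holder, ]
  fcen <- study$census[!study$census$harem_holder, ]
  harem_by <- split(harem[c("date", "easting", "northing")],
                    harem$individual_id)
  fcen_by <- split(fcen[c("date", "easting", "northing")],
                   fcen$individual_id)
  d_sire <- vapply(seq_len(nrow(truth)), function(k) {
    cd <- truth$conception_date[k]
    fr <- fcen_by[[truth$female_id[k]]]
    fr <- fr[fr$date == cd, ]
    if (is.null(fr) || !nrow(fr)) return(NA_real_)
    hr <- harem_by[[truth$sire_id[k]]]
    if (is.null(hr)) return(NA_real_)
    hr <- hr[abs(as.numeric(hr$date - cd)) <= WINDOW_HALF_DAYS, ]
    if (!nrow(hr)) return(NA_real_)
    j <- which.min(abs(as.numeric(hr$date - cd)))
    sqrt((hr$easting[j] - fr$easting[1])^2 +
           (hr$northing[j] - fr$northing[1])^2)
  }, numeric(1))
  tibble::tibble(
    n_conceptions = nrow(truth),
    n_females = dplyr::n_distinct(truth$female_id),
    n_sires = dplyr::n_distinct(truth$sire_id),
    mean_breeding_years = mean(per_f$years),
    mean_distinct_mates = mean(per_f$mates),
    mean_sire_age = mean(sire_age, na.rm = TRUE),
    prop_sire_500m = mean(d_sire <= 500, na.rm = TRUE),
    prop_sire_100m = mean(d_sire <= 100, na.rm = TRUE)
  )
}

#' Write a synthetic study to CSV files
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_individuals(study$individuals, file.path(dir, "individuals.csv"))
  write_census(study$census, file.path(dir, "census.csv"))
  write_calvings(study$calvings, file.path(dir, "calvings.csv"))
  readr::write_csv(study$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
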