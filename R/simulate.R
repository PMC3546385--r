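#' @rdname run_ensemble
#' @export
simulate_pedigree <- function(observed, calvings, census, scheme,
                              seed = 1L, weights = NULL) {
  sch <- as_scheme(scheme)
  ctx <- ensemble_context(observed, calvings, census, sch, weights)
  set.seed(seed)
  draws <- draw_sires(ctx, 1L)
  new_sires <- ctx$male_ids[draws[, 1]]
  out <- as_pedigree(observed)
  idx <- match(ctx$focal$calf_id, out$id)
  out$father_id[idx] <- new_sires
  out <- pedigree(tibble::as_tibble(out))
  attr(out, "scheme") <- sch$name
  attr(out, "seed") <- seed
  attr(out, "replaced_sires") <- tibble::tibble(
    calf_id = ctx$focal$calf_id, sire_id = new_sires
  )
  attr(out, "widened") <- ctx$widened
  out
}

#' Simulation ensembles under a null mating scheme
#'
#' `simulate_pedigree()` draws one replicate pedigree: every focal calf
#' (a calf with an assigned sire in the observed pedigree) has its sire
#' re-drawn from the males eligible for its dam-year under the scheme,
#' uniformly or weight-proportionally, with replacement across calves;
#' mothers and calf metadata are unchanged. `run_ensemble()` repeats
#' this `n_replicates` times and computes the ten pedigree statistics
#' for every replicate.
#'
#' When a constrained scheme leaves a dam-year with no eligible male,
#' the constraint is widened for that dam-year only, in the order
#' `SPATIAL_100` to `SPATIAL_500` to `TEMPORAL` to `RANDOM`, stopping at
#' the first non-empty set; the widening is recorded in the result.
#'
#' @param observed The observed [pedigree()].
#' @param calvings,census Study tables.
#' @param scheme A [scheme()] or scheme name.
#' @param n_replicates Number of replicate pedigrees (default 1000).
#' @param seed Master seed; the same seed reproduces the ensemble
#'   bit-identically.
#' @param weights Optional weights (an `age_weight_fit` for
#'   `AGE_CORRECTED`, a `fit_lbs_weights()` tibble for `BS_CORRECTED`);
#'   fitted from the observed data when omitted.
#' @param stats Character vector of statistics to compute per replicate
#'   (subset of [STAT_NAMES]); restricting it skips the kinship pass
#'   when only mating statistics are needed.
#' @param engine `"fast"` (vectorised, default) or `"reference"`
#'   (calls [stat_block()] on each replicate pedigree). Both use the
#'   same sire draws and return identical statistics.
#' @return A `mating_ensemble` object: `$stats` is a tibble with one row
#'   per replicate, plus the scheme, seed, number of focal calves, and
#'   the fallback-widening log.
#' @export
run_ensemble <- function(observed, calvings, census, scheme,
                         n_replicates = 1000L, seed = 1L, weights = NULL,
                         stats = STAT_NAMES,
                         engine = c("fast", "reference")) {
  engine <- match.arg(engine)
  stats <- match.arg(stats, STAT_NAMES, several.ok = TRUE)
  sch <- as_scheme(scheme)
  ctx <- ensemble_context(observed, calvings, census, sch, weights)
  set.seed(seed)
  draws <- draw_sires(ctx, n_replicates)
  st <- if (engine == "fast") {
    ensemble_stats_fast(ctx, draws, stats)
  } else {
    ensemble_stats_reference(ctx, draws, stats, observed, calvings, census)
  }
  structure(
    list(scheme = sch$name, n_replicates = as.integer(n_replicates),
         seed = seed, n_focal = nrow(ctx$focal), widened = ctx$widened,
         stats = tibble::as_tibble(
           c(list(replicate = seq_len(n_replicates)), st)
         )),
    class = "mating_ensemble"
  )
}

#' @export
print.mating_ensemble <- function(x, ...) {
  cat("Null mating ensemble:", x$scheme, "\n")
  cat(" ", x$n_replicates, "replicates,", x$n_focal,
      "focal calves, seed", x$seed, "\n")
  print(glance(x))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mating_ensemble <- function(x, ...) {
  vals <- x$stats[setdiff(names(x$stats), "replicate")]
  tibble::tibble(
    statistic = names(vals),
    sim_mean = vapply(vals, mean, numeric(1)),
    sim_sd = vapply(vals, sd, numeric(1)),
    n_replicates = x$n_replicates,
    scheme = x$scheme
  )
}

#' @exportS3Method generics::tidy
tidy.mating_ensemble <- function(x, ...) {
  tidyr::pivot_longer(x$stats, -"replicate",
                      names_to = "statistic", values_to = "value")
}

# ---- internal machinery -----------------------------------------------

# Widening ladder for empty eligible sets, from most to least constrained.
widen_ladder <- function(start) {
  ladder <- c("SPATIAL_100", "SPATIAL_500", "TEMPORAL", "RANDOM")
  base <- if (start %in% c("AGE_CORRECTED", "BS_CORRECTED")) {
    "SPATIAL_100"
  } else {
    start
  }
  ladder[seq(match(base, ladder), length(ladder))]
}

# Precomputes everything the draws and statistics need: focal calves,
# integer-coded eligible sets (with fallback widening), sampling weights,
# and fixed cross-replicate lookups.
ensemble_context <- function(observed, calvings, census, sch, weights) {
  ped <- as_pedigree(observed)
  win <- oestrus_windows(calvings)
  cand <- candidate_table(census, calvings)

  focal <- tibble::tibble(
    calf_id = ped$id, female_id = ped$mother_id, sire_obs = ped$father_id
  ) |>
    dplyr::filter(!is.na(.data$sire_obs))
  if (any(is.na(focal$female_id))) {
    stop("focal calf with a sire but no dam", call. = FALSE)
  }
  focal <- dplyr::inner_join(
    focal,
    dplyr::select(win, "calf_id", "rut_year", "conception_date",
                  "window_start", "window_end"),
    by = "calf_id"
  )
  if (nrow(focal) == 0) stop("no focal calves with assigned sires",
                             call. = FALSE)

  cand_by_year <- setNames(cand$candidate_males, cand$rut_year)
  harem <- census[census$harem_holder, ]
  harem_by_year <- split(
    harem[c("date", "individual_id", "easting", "northing")], harem$rut_year
  )
  fem_census <- census[census$individual_id %in% unique(focal$female_id), ]
  fem_by_id <- split(fem_census[c("date", "easting", "northing")],
                     fem_census$individual_id)

  ladder <- widen_ladder(sch$name)
  elig <- vector("list", nrow(focal))
  level_used <- character(nrow(focal))
  for (i in seq_len(nrow(focal))) {
    yr <- as.character(focal$rut_year[i])
    cand_y <- cand_by_year[[yr]]
    if (is.null(cand_y) || !length(cand_y)) {
      stop("no candidate males in rut year ", yr, call. = FALSE)
    }
    hy <- harem_by_year[[yr]]
    set <- character()
    for (lev in ladder) {
      set <- eligible_at_level(lev, focal[i, ], cand_y, hy,
                               fem_by_id[[focal$female_id[i]]])
      if (length(set)) {
        level_used[i] <- lev
        break
      }
    }
    if (!length(set)) stop("empty eligible set even under RANDOM",
                           call. = FALSE)
    elig[[i]] <- set
  }

  male_ids <- sort(unique(c(unlist(cand$candidate_males), focal$sire_obs)))
  elig_codes <- lapply(elig, match, male_ids)

  w <- ensemble_weights(sch, weights, ped, calvings, census,
                        focal, elig, male_ids)

  widened <- tibble::as_tibble(table(level = level_used)) |>
    dplyr::rename(n_dam_years = "n")

  # fixed lookups for the replicate statistics
  dam_ids <- sort(unique(focal$female_id))
  di <- match(focal$female_id, dam_ids)
  nf <- length(dam_ids)
  nm <- length(male_ids)
  fem_years <- split(win$rut_year, win$female_id)
  male_years <- split(harem$rut_year, harem$individual_id)
  omulti <- matrix(FALSE, nf, nm)
  for (a in seq_len(nf)) {
    fy <- unique(fem_years[[dam_ids[a]]])
    for (b in seq_len(nm)) {
      my <- male_years[[male_ids[b]]]
      if (!is.null(my) &&
            length(intersect(fy, unique(my))) >= 2) omulti[a, b] <- TRUE
    }
  }
  ml_tbl <- matrilines(ped)
  ml <- ml_tbl$matriline[match(dam_ids, ml_tbl$id)]
  ml <- ifelse(is.na(ml), paste0(".self.", dam_ids), ml)
  ml_code <- match(ml, unique(ml))

  list(ped = ped, focal = focal, elig_codes = elig_codes, weights = w,
       male_ids = male_ids, dam_ids = dam_ids, di = di, nf = nf, nm = nm,
       omulti_flat = as.vector(t(omulti)), ml_code = ml_code,
       widened = widened, sch = sch)
}

eligible_at_level <- function(level, frow, cand_y, harem_y, fem_rec) {
  if (level == "RANDOM") return(cand_y)
  if (is.null(harem_y) || !nrow(harem_y)) return(character())
  inwin <- harem_y$date >= frow$window_start & harem_y$date <= frow$window_end
  hw <- harem_y[inwin & harem_y$individual_id %in% cand_y, ]
  if (!nrow(hw)) return(character())
  if (level == "TEMPORAL") return(sort(unique(hw$individual_id)))
  r <- if (level == "SPATIAL_100") 100 else 500
  if (is.null(fem_rec)) return(character())
  fr <- fem_rec[fem_rec$date >= frow$window_start &
                  fem_rec$date <= frow$window_end, ]
  if (!nrow(fr)) return(character())
  k <- which.min(abs(as.numeric(fr$date - frow$conception_date)))
  d <- sqrt((hw$easting - fr$easting[k])^2 + (hw$northing - fr$northing[k])^2)
  sort(unique(hw$individual_id[d <= r]))
}

# Per-calf sampling weights over the eligible set (NULL for uniform).
ensemble_weights <- function(sch, weights, ped, calvings, census,
                             focal, elig, male_ids) {
  if (sch$weighting == "uniform") return(NULL)
  if (sch$weighting == "age") {
    fit <- if (is.null(weights)) {
      fit_age_weights(abs_records(ped, calvings, census))
    } else {
      weights
    }
    birth <- setNames(ped$birth_year, ped$id)
    lapply(seq_along(elig), function(i) {
      age <- focal$rut_year[i] - birth[elig[[i]]]
      w <- fit$weight(age)
      w[is.na(w)] <- fit$eps
      unname(w)
    })
  } else {
    tbl <- if (is.null(weights)) {
      fit_lbs_weights(abs_records(ped, calvings, census),
                      candidate_males = male_ids)
    } else {
      weights
    }
    wv <- setNames(tbl$weight, tbl$male_id)
    lapply(elig, function(el) {
      w <- unname(wv[el])
      w[is.na(w)] <- WEIGHT_EPS
      w
    })
  }
}

# Calf x replicate matrix of sire codes. Draw order is fixed (one row of
# draws per focal calf, in focal order), so a given master seed yields a
# bit-identical ensemble.
draw_sires <- function(ctx, n_rep) {
  n <- nrow(ctx$focal)
  draws <- matrix(0L, n, n_rep)
  for (i in seq_len(n)) {
    el <- ctx$elig_codes[[i]]
    draws[i, ] <- if (length(el) == 1L) {
      rep(el, n_rep)
    } else {
      sample(el, n_rep, replace = TRUE, prob = ctx$weights[[i]])
    }
  }
  draws
}

ensemble_stats_fast <- function(ctx, draws, stats) {
  n_rep <- ncol(draws)
  out <- lapply(stats, function(s) numeric(n_rep))
  names(out) <- stats
  need_mating <- any(stats %in% STAT_NAMES[1:6])
  need_kin <- any(stats %in% STAT_NAMES[7:10])

  di <- ctx$di
  nm <- ctx$nm
  nd_calves <- tabulate(di, nbins = ctx$nf)

  if (need_kin) {
    kin <- kinship_context(ctx)
    bt <- kinship_stats_batch_cpp(
      kin$father, kin$mother, kin$focal_pos - 1L,
      matrix(kin$male_pos[draws], nrow = nrow(draws))
    )
    for (s in intersect(stats, names(bt))) out[[s]] <- bt[[s]]
  }

  if (!need_mating) return(out[stats])

  for (r in seq_len(n_rep)) {
    s <- draws[, r]
    if (need_mating) {
      key <- (di - 1L) * nm + s
      dup <- duplicated(key)
      uk <- key[!dup]
      remated <- unique(key[dup])
      dam_uk <- (uk - 1L) %/% nm + 1L
      male_uk <- (uk - 1L) %% nm + 1L
      multi <- ctx$omulti_flat[uk]
      if ("pct_pairs_remating" %in% stats) {
        out$pct_pairs_remating[r] <- pct_safe(length(remated), sum(multi))
      }
      if ("pct_females_remating" %in% stats) {
        out$pct_females_remating[r] <- pct_safe(
          length(unique((remated - 1L) %/% nm + 1L)),
          length(unique(dam_uk[multi]))
        )
      }
      if ("pct_males_remating" %in% stats) {
        out$pct_males_remating[r] <- pct_safe(
          length(unique((remated - 1L) %% nm + 1L)),
          length(unique(male_uk[multi]))
        )
      }
      if ("mean_full_sibship" %in% stats) {
        out$mean_full_sibship[r] <- length(key) / length(uk)
      }
      if ("mate_diversity" %in% stats) {
        ds <- tabulate(dam_uk, nbins = ctx$nf)
        keep <- nd_calves > 0
        out$mate_diversity[r] <- mean(ds[keep] / nd_calves[keep])
      }
      if ("intralineage_ratio" %in% stats) {
        mkey <- (male_uk - 1L) * max(ctx$ml_code) + ctx$ml_code[dam_uk]
        uk2 <- !duplicated(mkey)
        n_ml <- tabulate(male_uk[uk2], nbins = nm)
        n_mates <- tabulate(male_uk, nbins = nm)
        keep <- n_mates > 0
        out$intralineage_ratio[r] <- mean(n_ml[keep] / n_mates[keep])
      }
    }
  }
  out[stats]
}

pct_safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_

# Sorted-pedigree context reused across replicates for the kinship pass.
# The sort must put every possible sire before its calf; the observed
# topological order is checked against all eligible sires and rebuilt
# from birth years if needed.
kinship_context <- function(ctx) {
  ped <- ctx$ped
  px <- parent_index(ped)
  pos <- match(ped$id, px$ids)
  focal_pos <- pos[match(ctx$focal$calf_id, ped$id)]
  male_pos <- pos[match(ctx$male_ids, ped$id)] - 1L
  max_sire_pos <- vapply(ctx$elig_codes, function(el) {
    max(male_pos[el])
  }, numeric(1))
  if (any(max_sire_pos >= focal_pos - 1L)) {
    ord <- order(ped$birth_year, ped$id, na.last = TRUE)
    ids <- ped$id[ord]
    px <- list(ids = ids,
               father = match(ped$father_id[ord], ids) - 1L,
               mother = match(ped$mother_id[ord], ids) - 1L)
    pos <- match(ped$id, ids)
    focal_pos <- pos[match(ctx$focal$calf_id, ped$id)]
    male_pos <- pos[match(ctx$male_ids, ped$id)] - 1L
    max_sire_pos <- vapply(ctx$elig_codes, function(el) {
      max(male_pos[el])
    }, numeric(1))
    if (any(max_sire_pos >= focal_pos - 1L)) {
      stop("an eligible sire is not older than the focal calf; ",
           "kinship statistics need strictly parent-first birth years",
           call. = FALSE)
    }
  }
  list(father = px$father, mother = px$mother,
       focal_pos = focal_pos, male_pos = male_pos)
}

ensemble_stats_reference <- function(ctx, draws, stats, observed,
                                     calvings, census) {
  ml_tbl <- matrilines(as_pedigree(observed))
  rows <- lapply(seq_len(ncol(draws)), function(r) {
    ped_r <- as_pedigree(observed)
    idx <- match(ctx$focal$calf_id, ped_r$id)
    ped_r$father_id[idx] <- ctx$male_ids[draws[, r]]
    ped_r <- pedigree(tibble::as_tibble(ped_r))
    stat_block(ped_r, calvings, census, ml_tbl)[stats]
  })
  as.list(dplyr::bind_rows(rows))
}
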