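#' One-tailed Z test against a simulation envelope
#'
#' Compares an observed statistic to the mean and standard deviation of
#' its value over the simulation replicates: z = (observed - mean) / sd
#' with the sample SD (denominator n - 1), and a one-tailed standard
#' normal tail probability in the stated direction (no continuity
#' correction).
#'
#' @param observed Observed value of the statistic.
#' @param sim_values Numeric vector of the statistic over the replicates
#'   (at least 2 values with positive SD).
#' @param direction `"greater"` (upper tail: is the observed value
#'   larger than the null?) or `"less"`.
#' @param sim_mean,sim_sd Optionally supply the envelope moments
#'   directly instead of `sim_values` (used when reconstructing tests
#'   from published summaries).
#' @return A one-row tibble of class `rut_ztest`: `observed`,
#'   `sim_mean`, `sim_sd`, `z`, `p_one_tailed`, `direction`.
#' @examples
#' z_test(9.20, sim_mean = 6.97, sim_sd = 0.54, direction = "greater")
#' @export
z_test <- function(observed, sim_values = NULL,
                   direction = c("greater", "less"),
                   sim_mean = NULL, sim_sd = NULL) {
  direction <- match.arg(direction)
  if (is.null(sim_mean)) {
    if (is.null(sim_values) || length(sim_values) < 2) {
      stop("need >= 2 simulated values (or explicit sim_mean/sim_sd)",
           call. = FALSE)
    }
    sim_mean <- mean(sim_values)
    sim_sd <- sd(sim_values)
  }
  if (!is.finite(sim_sd) || sim_sd <= 0) {
    stop("simulation envelope has zero or undefined SD; Z test undefined",
         call. = FALSE)
  }
  z <- (observed - sim_mean) / sim_sd
  p <- if (direction == "greater") {
    pnorm(z, lower.tail = FALSE)
  } else {
    pnorm(z, lower.tail = TRUE)
  }
  out <- tibble::tibble(
    observed = observed, sim_mean = sim_mean, sim_sd = sim_sd,
    z = z, p_one_tailed = max(p, .Machine$double.xmin),
    direction = direction
  )
  class(out) <- c("rut_ztest", class(out))
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of tests in the hypothesis family (>= 1).
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return The per-test threshold `family_alpha / n_tests`.
#' @examples
#' bonferroni_alpha(18) # 0.00278, reported as 0.003
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  family_alpha / n_tests
}

#' Default test plan for the ten statistics
#'
#' One row per statistic with its one-tailed direction (greater for the
#' re-mating percentages, sibship size, relatedness and the inbreeding
#' summaries; less for the two diversity ratios, where nonrandom mating
#' pushes the ratio down) and its hypothesis family. Within a family the
#' Bonferroni correction counts every (statistic, scheme) test: the
#' three re-mating percentages over six schemes form an 18-test family,
#' each single-statistic family over six schemes a 6-test family, and
#' the three inbreeding summaries an 18-test family.
#'
#' @return A tibble with columns `statistic`, `direction`, `family`.
#' @export
default_test_plan <- function() {
  tibble::tribble(
    ~statistic, ~direction, ~family,
    "pct_pairs_remating", "greater", "remating",
    "pct_females_remating", "greater", "remating",
    "pct_males_remating", "greater", "remating",
    "mean_full_sibship", "greater", "sibship",
    "mate_diversity", "less", "mate_diversity",
    "intralineage_ratio", "less", "intralineage",
    "mean_relatedness", "greater", "relatedness",
    "mean_f", "greater", "inbreeding",
    "n_f_nonzero", "greater", "inbreeding",
    "n_f_close", "greater", "inbreeding"
  )
}

#' Compare an observed pedigree to every null scheme
#'
#' Runs one one-tailed Z test per (statistic, scheme) pair in the test
#' plan, with a Bonferroni threshold per hypothesis family (the family
#' size is the number of tests actually present in that family).
#'
#' @param observed_block One-row tibble from [stat_block()] on the
#'   observed pedigree.
#' @param ensembles Named list of [run_ensemble()] results, one per
#'   scheme.
#' @param plan Test plan tibble (`statistic`, `direction`, `family`);
#'   defaults to [default_test_plan()] restricted to statistics present
#'   in both the observed block and the ensembles.
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return A tibble of class `scheme_comparison` with one row per
#'   (statistic, scheme): observed value, envelope mean and SD, `z`,
#'   `p_one_tailed`, `n_tests`, `alpha_bonferroni`, `significant`.
#' @export
compare_schemes <- function(observed_block, ensembles,
                            plan = default_test_plan(),
                            family_alpha = 0.05) {
  if (is.null(names(ensembles))) {
    names(ensembles) <- vapply(ensembles, function(e) e$scheme, "")
  }
  avail <- Reduce(intersect, lapply(ensembles, function(e) {
    setdiff(names(e$stats), "replicate")
  }))
  plan <- plan[plan$statistic %in% intersect(avail, names(observed_block)), ]
  if (!nrow(plan)) stop("no statistic in the plan is available",
                        call. = FALSE)
  rows <- purrr::pmap(
    list(rep(plan$statistic, each = length(ensembles)),
         rep(plan$direction, each = length(ensembles)),
         rep(plan$family, each = length(ensembles)),
         rep(names(ensembles), times = nrow(plan))),
    function(stat, dir, fam, sch) {
      vals <- ensembles[[sch]]$stats[[stat]]
      zt <- z_test(observed_block[[stat]], vals, direction = dir)
      tibble::tibble(statistic = stat, scheme = sch, family = fam,
                     observed = zt$observed, sim_mean = zt$sim_mean,
                     sim_sd = zt$sim_sd, z = zt$z,
                     p_one_tailed = zt$p_one_tailed, direction = dir)
    }
  )
  out <- dplyr::bind_rows(rows)
  fam_n <- dplyr::count(out, .data$family, name = "n_tests")
  out <- dplyr::left_join(out, fam_n, by = "family")
  out$alpha_bonferroni <- family_alpha / out$n_tests
  out$significant <- out$p_one_tailed < out$alpha_bonferroni
  class(out) <- c("scheme_comparison", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.scheme_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.scheme_comparison <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    n_families = dplyr::n_distinct(x$family)
  )
}

#' Render p values in report style
#'
#' Formats small p values as `"< 0.0001"`, the convention used in the
#' published comparison tables.
#'
#' @param p Numeric vector of p values.
#' @param floor Values below this print as `"< floor"` (default 1e-4).
#' @return Character vector.
#' @export
format_p <- function(p, floor = 1e-4) {
  ifelse(p < floor, paste("<", format(floor, scientific = FALSE)),
         formatC(p, digits = 3, format = "g"))
}
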