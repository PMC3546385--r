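#' Plot a simulation ensemble against an observed value
#'
#' Histogram of one statistic over the replicates, with the observed
#' value marked; a simulation-envelope figure.
#'
#' @param object A [run_ensemble()] result.
#' @param statistic Which statistic to plot (default the pair re-mating
#'   percentage).
#' @param observed Optional observed value drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mating_ensemble <- function(object,
                                     statistic = "pct_pairs_remating",
                                     observed = NULL, ...) {
  if (!statistic %in% names(object$stats)) {
    stop("statistic not in ensemble: ", statistic, call. = FALSE)
  }
  p <- ggplot2::ggplot(object$stats,
                       ggplot2::aes(x = .data[[statistic]])) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::labs(
      x = statistic, y = "replicates",
      title = paste0(object$scheme, " null ensemble (",
                     object$n_replicates, " replicates)")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed,
                                 colour = "firebrick", linewidth = 1)
  }
  p
}

#' Plot observed statistics against every null scheme
#'
#' One panel per statistic: the simulation envelope (mean and a 1.96 SD
#' band) per scheme, with the observed value as a horizontal line.
#'
#' @param object A [compare_schemes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scheme_comparison <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme, y = .data$sim_mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$sim_mean - 1.96 * .data$sim_sd,
                   ymax = .data$sim_mean + 1.96 * .data$sim_sd)
    ) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$observed),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "statistic (null mean ± 1.96 SD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot relatedness against rut-site distance for male pairs
#'
#' Scatter of the pairwise table with the fitted slope overlaid.
#'
#' @param object A [fit_relatedness_distance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spatial_fit <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$distance, y = .data$relatedness)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "firebrick") +
    ggplot2::labs(
      x = "pairwise rut-site distance (m)",
      y = "pairwise relatedness (2K)",
      subtitle = sprintf("slope %.3g per m, permutation p = %.3g",
                         object$slope, object$p_permutation)
    ) +
    ggplot2::theme_minimal()
}
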