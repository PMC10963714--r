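#' Plot relative-value histograms of a cross-OPE run
#'
#' Density histograms of the policy-minus-behaviour relative values,
#' faceted by evaluation reward version, for the requested round(s) —
#' the standard view of the two-round selection outcome.
#'
#' @param object A `cross_ope_matrix` from [cross_ope()].
#' @param rounds Rounds to include (default both).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @returns A ggplot.
#' @export
autoplot.cross_ope_matrix <- function(object, rounds = c(1, 2), bins = 20,
                                      ...) {
  df <- object[object$round %in% rounds, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relative_value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(!!rlang::sym("density"))),
                            bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~eval_version, scales = "free") +
    ggplot2::labs(x = "relative value (policy - behaviour)", y = "density",
                  title = "Cross-OPE relative values by reward version")
}

#' Plot an aggregate action surface
#'
#' Heatmap over the PEEP x FiO2 lattice of one aggregated statistic
#' (mean delta-Q by default); the NV action is shown as its own tile.
#'
#' @param object An `action_surface` from [aggregate_surfaces()].
#' @param statistic Column to fill by: `"mean_delta_q"`,
#'   `"mean_q_physician"`, `"mean_q_policy"` or `"count"`.
#' @param ... Unused.
#' @returns A ggplot.
#' @export
autoplot.action_surface <- function(object, statistic = "mean_delta_q",
                                    ...) {
  df <- object
  df$peep_lab <- ifelse(is.na(df$peep_bin), "NV", df$peep_bin)
  df$fio2_lab <- ifelse(is.na(df$fio2_bin), "NV", df$fio2_bin)
  df$peep_lab <- factor(df$peep_lab, levels = unique(df$peep_lab))
  df$fio2_lab <- factor(df$fio2_lab, levels = unique(df$fio2_lab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peep_lab, y = .data$fio2_lab,
                                   fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "PEEP bin (cmH2O)", y = "FiO2 bin (%)",
                  fill = statistic,
                  title = "Aggregate surface by physician action")
}

#' Plot per-action Q-value distributions
#'
#' @param data Output of [q_distribution_per_action()].
#' @returns A ggplot of frequency polygons, one per action.
#' @export
plot_q_distributions <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$bin_mid, y = .data$count,
                                     colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Q-value", y = "frequency", colour = "action",
                  title = "Q-value distribution per action")
}

#' Plot a trajectory's delta-Q series
#'
#' PEEP/FiO2 action path over time coloured by the signed log delta-Q —
#' the flat (2D) analogue of the 3D trajectory view, suitable for spotting
#' abrupt hue shifts that warrant reassessment.
#'
#' @param series Output of [trajectory_series()].
#' @returns A ggplot.
#' @export
plot_trajectory_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time_h,
                                       y = .data$physician_action,
                                       colour = .data$log_delta_q)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_gradient2(low = "firebrick", mid = "grey80",
                                    high = "seagreen", midpoint = 0) +
    ggplot2::labs(x = "hour", y = "physician action index",
                  colour = "log delta-Q",
                  title = "Per-trajectory delta-Q series")
}
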