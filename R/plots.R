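# ggplot2 helpers for the main result types.

#' Kaplan-Meier curves for a stratified survival result
#'
#' @param object A [stratified_survival()] result.
#' @param ... Unused.
#' @return A ggplot of the low/high step curves with the log-rank p and
#'   hazard ratio in the subtitle.
#' @method autoplot stratified_survival
#' @export
autoplot.stratified_survival <- function(object, ...) {
  km <- object$data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ km_estimate(.x$time, .x$event)) |>
    dplyr::ungroup()
  start <- dplyr::distinct(km, .data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  ggplot2::ggplot(dplyr::bind_rows(start, km),
                  ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "survival probability", colour = "expression",
      subtitle = sprintf("log-rank p = %s, HR (high vs low) = %s",
                         format_num(object$p), format_num(object$hr))
    ) +
    ggplot2::theme_minimal()
}

#' Linearized median-effect plot
#'
#' @param object A [median_effect_fit()].
#' @param ... Unused.
#' @return A ggplot of `log10(fa/(1-fa))` against `log10(dose)` with the
#'   fitted line.
#' @method autoplot median_effect_fit
#' @export
autoplot.median_effect_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$m,
                         intercept = -object$m * log10(object$dm)) +
    ggplot2::labs(x = "log10 dose", y = "log10(fa / (1 - fa))",
                  subtitle = sprintf("m = %s, Dm = %s, r = %s",
                                     format_num(object$m),
                                     format_num(object$dm),
                                     format_num(object$r))) +
    ggplot2::theme_minimal()
}

#' Combination-index plot
#'
#' @param combos Result of [combination_index()].
#' @return A ggplot of CI against fraction affected with the additivity line.
#' @export
plot_combination_index <- function(combos) {
  ggplot2::ggplot(combos, ggplot2::aes(.data$fa, .data$ci)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction affected", y = "combination index") +
    ggplot2::theme_minimal()
}

#' Normalized isobologram
#'
#' @param combos Result of [combination_index()].
#' @return A ggplot of the normalized dose coordinates with the additivity
#'   diagonal.
#' @export
plot_isobologram <- function(combos) {
  ggplot2::ggplot(combos, ggplot2::aes(.data$iso1, .data$iso2)) +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "d1 / Dx1(fa)", y = "d2 / Dx2(fa)") +
    ggplot2::coord_equal(xlim = c(0, NA), ylim = c(0, NA)) +
    ggplot2::theme_minimal()
}

#' Population proportions over stages
#'
#' @param props Result of [population_proportions()].
#' @return A ggplot of per-population proportion trajectories.
#' @export
plot_population_proportions <- function(props) {
  ggplot2::ggplot(props, ggplot2::aes(.data$stage, .data$proportion,
                                      colour = .data$population,
                                      group = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "disease stage", y = "proportion of cells") +
    ggplot2::theme_minimal()
}

#' Stage trajectories for selected genes
#'
#' @param tensor A [stage_tensor()].
#' @param genes Genes to draw.
#' @return A ggplot of mean expression across stages, one facet per gene,
#'   coloured by population.
#' @export
plot_trajectories <- function(tensor, genes) {
  dat <- tensor[tensor$gene %in% genes, ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$stage, .data$mean_expr,
                                    colour = .data$population,
                                    group = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "disease stage", y = "mean log-normalized expression") +
    ggplot2::theme_minimal()
}
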