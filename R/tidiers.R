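# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn median_effect_fit Tidy the fitted parameters.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy median_effect_fit
#' @export
tidy.median_effect_fit <- function(x, ...) {
  tibble::tibble(term = c("m", "dm", "r"),
                 estimate = c(x$m, x$dm, x$r))
}

#' @describeIn median_effect_fit One-row model summary.
#' @method glance median_effect_fit
#' @export
glance.median_effect_fit <- function(x, ...) {
  tibble::tibble(m = x$m, dm = x$dm, r = x$r, n = x$n)
}

#' @describeIn stratified_survival Per-group subject and event counts.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy stratified_survival
#' @export
tidy.stratified_survival <- function(x, ...) {
  x$data |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$event),
                     median_time = stats::median(.data$time),
                     .groups = "drop")
}

#' @describeIn stratified_survival One-row test summary.
#' @method glance stratified_survival
#' @export
glance.stratified_survival <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, n_low = x$n_low, n_high = x$n_high,
                 chi2 = x$chi2, p = x$p, hr = x$hr,
                 hr_lo = x$hr_ci[1], hr_hi = x$hr_ci[2])
}
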