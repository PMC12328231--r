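# Chou-Talalay median-effect analysis: linearized fit, effective doses,
# combination index and normalized isobologram coordinates.

#' Fit the median-effect equation
#'
#' Ordinary least squares on the linearized median-effect form
#' `log10(fa / (1 - fa)) = m * (log10(D) - log10(Dm))`: the slope is the
#' Hill-like exponent `m`, the x-intercept gives the median-effect dose `Dm`,
#' and `r` is the Pearson correlation of the linearized fit. Fractions
#' affected of exactly 0 or 1 are rejected (the linearization is unbounded
#' there).
#'
#' @param data Data frame with dose and fraction-affected columns.
#' @param dose,fa Column names (tidy-eval) holding positive doses and
#'   fractions affected in (0, 1).
#' @return A `median_effect_fit` object with `m`, `dm`, `r`, `n`, and the
#'   fitted points.
#' @export
median_effect_fit <- function(data, dose = dose, fa = fa) {
  d <- dplyr::pull(data, {{ dose }})
  f <- dplyr::pull(data, {{ fa }})
  if (length(d) < 2) stop("need at least 2 dose points", call. = FALSE)
  if (any(d <= 0)) stop("doses must be positive", call. = FALSE)
  bad <- which(f <= 0 | f >= 1)
  if (length(bad) > 0) {
    stop("fraction affected outside (0, 1) at point(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- log10(d)
  y <- log10(f / (1 - f))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m == 0) stop("degenerate fit: slope is zero or undefined",
                                    call. = FALSE)
  dm <- 10^(-unname(stats::coef(fit)[1]) / m)
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  structure(list(m = m, dm = dm, r = r, n = length(d),
                 points = tibble::tibble(dose = d, fa = f, x = x, y = y)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("<median_effect_fit> m =", format_num(x$m), " Dm =", format_num(x$dm),
      " r =", format_num(x$r), sprintf(" (n = %d)\n", x$n))
  invisible(x)
}

#' Effective dose for a fraction affected
#'
#' `Dx = Dm * (fa / (1 - fa))^(1/m)` — the single-agent dose producing
#' effect `fa` under the fitted median-effect curve.
#'
#' @param fit A [median_effect_fit()].
#' @param fa Fraction(s) affected, strictly inside (0, 1).
#' @return Numeric vector of doses.
#' @export
effective_dose <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) {
    stop("fraction affected must lie strictly in (0, 1)", call. = FALSE)
  }
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index
#'
#' For each combination `(d1, d2)` with measured fraction affected `fa`:
#' `CI = d1 / Dx1(fa) + d2 / Dx2(fa)`, the two addends being the normalized
#' isobologram coordinates. CI below 1 indicates synergy, 1 additivity,
#' above 1 antagonism.
#'
#' @param fit1,fit2 Single-agent [median_effect_fit()]s.
#' @param combos Data frame with columns `d1`, `d2`, `fa`.
#' @return Tibble `d1`, `d2`, `fa`, `iso1`, `iso2`, `ci`, `interpretation`.
#' @export
combination_index <- function(fit1, fit2, combos) {
  stopifnot(all(c("d1", "d2", "fa") %in% names(combos)))
  iso1 <- combos$d1 / effective_dose(fit1, combos$fa)
  iso2 <- combos$d2 / effective_dose(fit2, combos$fa)
  ci <- iso1 + iso2
  tibble::tibble(
    d1 = combos$d1, d2 = combos$d2, fa = combos$fa,
    iso1 = iso1, iso2 = iso2, ci = ci,
    interpretation = dplyr::case_when(
      abs(ci - 1) < 1e-9 ~ "additive",
      ci < 1 ~ "synergy",
      TRUE ~ "antagonism"
    )
  )
}
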