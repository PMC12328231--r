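# Expression-stratified survival analysis: median split, Kaplan-Meier,
# log-rank, O/E hazard ratio, and receptor prognostic prioritization.
# Estimators are computed through the survival package; the hazard ratio is
# the closed-form O/E (Pike) estimator from the log-rank expected counts.

#' Median split of an expression vector
#'
#' The cutoff is the sample median; subjects strictly below it form the low
#' group, subjects at or above it the high group (ties at the median go
#' high). With 161 distinct values this gives the 80 / 81 split convention.
#'
#' @param expression Numeric vector, at least 2 subjects.
#' @return List with `cutoff`, `group` (factor `low`/`high`), `n_low`,
#'   `n_high`.
#' @export
median_split <- function(expression) {
  if (length(expression) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (length(unique(expression)) == 1) {
    stop("all expression values identical: degenerate split", call. = FALSE)
  }
  cutoff <- stats::median(expression)
  group <- factor(ifelse(expression < cutoff, "low", "high"),
                  levels = c("low", "high"))
  list(cutoff = cutoff, group = group,
       n_low = sum(group == "low"), n_high = sum(group == "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `surv` over the
#'   distinct observed times.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty survival data", call. = FALSE)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv)
}

# survdiff wrapper returning observed/expected/variance for group 1.
logrank_components <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("exactly two nonempty groups required", call. = FALSE)
  }
  if (sum(event) == 0) {
    lv <- levels(droplevels(group))
    return(list(o = c(0, 0), e = c(0, 0), v = 0, levels = lv))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(o = as.numeric(sd$obs), e = as.numeric(sd$exp),
       v = sd$var[1, 1], levels = levels(droplevels(group)))
}

#' Two-group log-rank test
#'
#' Chi-square statistic `(O1 - E1)^2 / V` with the hypergeometric variance
#' accumulated over distinct event times, 1 degree of freedom.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level group labels.
#' @return List `chi2`, `p`, `obs`, `exp` (per group).
#' @export
logrank <- function(time, event, group) {
  lc <- logrank_components(time, event, group)
  diff1 <- lc$o[1] - lc$e[1]
  if (lc$v == 0 || !is.finite(lc$v)) {
    if (abs(diff1) < 1e-12) {
      chi2 <- 0
    } else {
      stop("log-rank variance is zero but observed != expected", call. = FALSE)
    }
  } else {
    chi2 <- diff1^2 / lc$v
  }
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       obs = lc$o, exp = lc$e)
}

#' O/E (Pike) hazard-ratio estimate
#'
#' `HR = (O1/E1) / (O2/E2)` with 95% CI
#' `exp(log HR +/- 1.96 * sqrt(1/E1 + 1/E2))`, using the log-rank expected
#' event counts. Group 1 is the first factor level of `group`.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level group labels.
#' @return List `hr`, `ci` (length-2), `obs`, `exp`.
#' @export
hazard_ratio <- function(time, event, group) {
  lc <- logrank_components(time, event, group)
  if (any(lc$e == 0)) stop("zero expected events in a group", call. = FALSE)
  if (any(lc$o == 0)) {
    # O/E of 0 gives hr 0 or Inf; keep it but the CI is undefined
    hr <- (lc$o[1] / lc$e[1]) / (lc$o[2] / lc$e[2])
    return(list(hr = hr, ci = c(NA_real_, NA_real_), obs = lc$o, exp = lc$e))
  }
  hr <- (lc$o[1] / lc$e[1]) / (lc$o[2] / lc$e[2])
  se <- sqrt(1 / lc$e[1] + 1 / lc$e[2])
  list(hr = hr, ci = exp(log(hr) + c(-1.96, 1.96) * se),
       obs = lc$o, exp = lc$e)
}

#' Expression-stratified survival analysis
#'
#' Splits subjects at the median expression (or a supplied cutoff), then runs
#' the log-rank test and the O/E hazard-ratio estimate of high vs low.
#'
#' @param data Tibble with `time`, `event`, `expression` columns.
#' @param cutoff Optional fixed cutoff; default is the sample median.
#' @return A `stratified_survival` object: `cutoff`, `n_low`, `n_high`,
#'   `chi2`, `p`, `hr` (high vs low), `hr_ci`, and the per-subject `data`
#'   with its `group`.
#' @export
stratified_survival <- function(data, cutoff = NULL) {
  stopifnot(all(c("time", "event", "expression") %in% names(data)))
  if (is.null(cutoff)) {
    ms <- median_split(data$expression)
  } else {
    group <- factor(ifelse(data$expression < cutoff, "low", "high"),
                    levels = c("low", "high"))
    if (nlevels(droplevels(group)) != 2) {
      stop("cutoff leaves an empty group", call. = FALSE)
    }
    ms <- list(cutoff = cutoff, group = group,
               n_low = sum(group == "low"), n_high = sum(group == "high"))
  }
  # group order: high first so HR is high vs low
  g <- factor(ms$group, levels = c("high", "low"))
  lr <- logrank(data$time, data$event, g)
  hr <- hazard_ratio(data$time, data$event, g)
  structure(list(
    cutoff = ms$cutoff, n_low = ms$n_low, n_high = ms$n_high,
    chi2 = lr$chi2, p = lr$p, hr = hr$hr, hr_ci = hr$ci,
    data = dplyr::mutate(data, group = ms$group)
  ), class = "stratified_survival")
}

#' @export
print.stratified_survival <- function(x, ...) {
  cat("<stratified_survival> cutoff", format_num(x$cutoff),
      sprintf("(low n=%d, high n=%d)\n", x$n_low, x$n_high))
  cat("  log-rank chi2 =", format_num(x$chi2), " p =", format_num(x$p), "\n")
  cat("  HR (high vs low) =", format_num(x$hr),
      sprintf("[%s, %s]\n", format_num(x$hr_ci[1]), format_num(x$hr_ci[2])))
  invisible(x)
}

#' Prognostic prioritization of receptors
#'
#' For each receptor with a survival table: median split, log-rank test, and
#' O/E hazard ratio. Receptors are ranked by raw p; the poor-prognosis flag
#' requires an adjusted p below `alpha` (BH across the tested panel by
#' default) together with `hr > 1` — a protective association is never
#' flagged.
#'
#' @param surv_table Long tibble `gene`, `time`, `event`, `expression`.
#' @param genes Receptors to test (default: all genes present).
#' @param alpha Significance level for the flag.
#' @param adjust `"BH"` (default) adjusts across the tested panel; `"none"`
#'   flags on raw p.
#' @return Tibble ranked by p: `gene`, `cutoff`, `n_low`, `n_high`, `chi2`,
#'   `p`, `padj`, `hr`, `hr_lo`, `hr_hi`, `poor_prognosis`.
#' @export
prioritize_receptors <- function(surv_table, genes = NULL, alpha = 0.05,
                                 adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  genes <- genes %||% unique(surv_table$gene)
  rows <- lapply(genes, function(g) {
    d <- surv_table[surv_table$gene == g, ]
    if (nrow(d) == 0) stop("no survival rows for gene ", g, call. = FALSE)
    s <- stratified_survival(d)
    tibble::tibble(gene = g, cutoff = s$cutoff, n_low = s$n_low,
                   n_high = s$n_high, chi2 = s$chi2, p = s$p, hr = s$hr,
                   hr_lo = s$hr_ci[1], hr_hi = s$hr_ci[2])
  })
  out <- dplyr::bind_rows(rows)
  out$padj <- if (adjust == "BH") bh_adjust(out$p) else out$p
  out$poor_prognosis <- out$padj < alpha & out$hr > 1
  out[order(out$p), c("gene", "cutoff", "n_low", "n_high", "chi2", "p",
                      "padj", "hr", "hr_lo", "hr_hi", "poor_prognosis")]
}
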