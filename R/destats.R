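#' Counts-per-million normalization
#'
#' Scales each sample (column) of a gene-by-sample count matrix to a library
#' size of one million. Downstream tests work on `log2(cpm + 1)`.
#'
#' @param counts Non-negative numeric matrix, genes in rows, samples in
#'   columns, gene identifiers as rownames.
#' @return A numeric matrix of the same shape with per-column sums of 1e6
#'   (all-zero rows stay zero).
#' @examples
#' m <- matrix(c(10, 90, 1, 1), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cpm_normalize(m)
#' @export
cpm_normalize <- function(counts) {
  assert_count_matrix(counts)
  cs <- colSums(counts)
  bad <- which(cs == 0)
  if (length(bad) > 0) {
    nm <- colnames(counts)[bad] %||% as.character(bad)
    stop("zero total counts in sample(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  t(t(counts) / cs) * 1e6
}

#' Two-group differential expression
#'
#' Per-gene Welch t-test on `log2(cpm + 1)` with a pseudocount fold-change,
#' and Benjamini-Hochberg adjustment across genes. This is a transparent
#' normal-theory test on log-normalized counts; fold-change is
#' `log2((mean_cpm_disease + 0.5) / (mean_cpm_control + 0.5))`.
#'
#' @param counts Gene-by-sample count matrix.
#' @param groups Two-level vector (length `ncol(counts)`) labelling samples.
#' @param control Label of the reference group. Defaults to the first level of
#'   `factor(groups)`; the other level is treated as disease.
#' @return A tibble with one row per gene: `gene`, `log2fc`, `p`, `padj`.
#' @export
de_test <- function(counts, groups, control = NULL) {
  assert_count_matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) {
    stop("`groups` must label every sample column", call. = FALSE)
  }
  lv <- unique(groups)
  if (length(lv) != 2) stop("`groups` must have exactly two levels", call. = FALSE)
  control <- control %||% sort(lv)[1]
  if (!control %in% lv) stop("`control` is not a level of `groups`", call. = FALSE)
  disease <- setdiff(lv, control)
  i1 <- which(groups == disease)
  i0 <- which(groups == control)
  if (length(i1) < 2 || length(i0) < 2) {
    stop("each group needs at least 2 samples (variance undefined otherwise)",
         call. = FALSE)
  }

  cpm <- cpm_normalize(counts)
  lc <- log2(cpm + 1)
  n1 <- length(i1); n0 <- length(i0)
  m1 <- rowMeans(lc[, i1, drop = FALSE]); v1 <- row_vars(lc[, i1, drop = FALSE])
  m0 <- rowMeans(lc[, i0, drop = FALSE]); v0 <- row_vars(lc[, i0, drop = FALSE])
  se2 <- v1 / n1 + v0 / n0
  tstat <- ifelse(se2 == 0, 0, (m1 - m0) / sqrt(se2))
  df <- ifelse(se2 == 0, Inf,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)))
  p <- ifelse(se2 == 0,
              ifelse(m1 == m0, 1, 0),
              2 * stats::pt(-abs(tstat), df))
  log2fc <- log2((rowMeans(cpm[, i1, drop = FALSE]) + 0.5) /
                   (rowMeans(cpm[, i0, drop = FALSE]) + 0.5))
  tibble::tibble(
    gene = rownames(counts),
    log2fc = unname(log2fc),
    p = unname(p),
    padj = bh_adjust(unname(p))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-down false-discovery-rate correction: the i-th smallest p-value maps to
#' `min_{j >= i}(p_(j) * m / j)` capped at 1, returned in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  assert_probability(pvalues, "pvalues")
  stats::p.adjust(pvalues, method = "BH")
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Mid-rank ties. For small pooled samples (`n1 + n2 <= 10` by default) the
#' two-sided p-value is exact, by enumeration of all labelings of the pooled
#' values: `p = P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|)`. Otherwise a normal
#' approximation with tie correction and continuity correction is used. Under
#' the enumeration convention two identical samples give p = 1.
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param exact Force the exact enumeration on or off; default enumerates when
#'   `length(x) + length(y) <= 10`.
#' @return A list with `statistic` (U for `x`), `p`, and `method`.
#' @export
rank_sum <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  exact <- exact %||% (n <= 10)

  if (exact) {
    labelings <- utils::combn(n, n1)
    rank_sums <- colSums(matrix(r[labelings], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(statistic = unname(u_obs), p = p, method = method)
}

#' Hypergeometric over-representation
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set and
#' an annotated gene set within a finite universe:
#' `p = P(X >= overlap)` for X hypergeometric. Symmetric in (query, geneset).
#'
#' @param query,geneset Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return One-row tibble: `overlap`, `p`, `enrichment` (observed / expected
#'   overlap ratio).
#' @export
hypergeom_ora <- function(query, geneset, universe) {
  query <- unique(query); geneset <- unique(geneset); universe <- unique(universe)
  off_q <- setdiff(query, universe)
  if (length(off_q) > 0) {
    stop("query genes outside universe: ", paste(off_q, collapse = ", "),
         call. = FALSE)
  }
  off_g <- setdiff(geneset, universe)
  if (length(off_g) > 0) {
    stop("geneset genes outside universe: ", paste(off_g, collapse = ", "),
         call. = FALSE)
  }
  k <- length(intersect(query, geneset))
  n_u <- length(universe); n_g <- length(geneset); n_q <- length(query)
  p <- stats::phyper(k - 1, n_g, n_u - n_g, n_q, lower.tail = FALSE)
  expected <- n_q * n_g / n_u
  tibble::tibble(
    overlap = k,
    p = min(1, p),
    enrichment = if (expected > 0) k / expected else NA_real_
  )
}
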