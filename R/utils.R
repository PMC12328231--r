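# Internal helpers shared across modules.

# All generator randomness flows through one root seed per dataset; the global
# RNG state is never clobbered.
with_dataset_seed <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed) + as.integer(offset), code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(sprintf("`%s` must be a numeric matrix (genes in rows)", arg), call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    stop(sprintf("`%s` must have gene identifiers as rownames", arg), call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop(sprintf("`%s` has duplicated gene identifiers", arg), call. = FALSE)
  }
  if (any(counts < 0)) stop(sprintf("`%s` contains negative values", arg), call. = FALSE)
  invisible(counts)
}

assert_probability <- function(p, arg = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("`%s` must contain probabilities in [0, 1]", arg), call. = FALSE)
  }
  invisible(p)
}

# Row-wise variance without a matrixStats dependency.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("variance undefined with fewer than 2 columns", call. = FALSE)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# Fixed 6-significant-digit formatting for byte-stable text output.
format_num <- function(x) formatC(x, digits = 6, format = "g")
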