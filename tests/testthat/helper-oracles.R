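# Independent oracles, deliberately coded with different formulas than the
# implementation they check.

# Step-down BH by explicit min-scan from the largest p.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# U statistic by pair counting (not ranks): #{x_i > y_j} + 0.5 #{x_i == y_j}.
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided rank-sum p by exhaustive enumeration of labelings.
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  mu <- n1 * length(y) / 2
  u_obs <- oracle_u_stat(x, y)
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2, function(idx) {
    oracle_u_stat(pooled[idx], pooled[-idx])
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Log-rank O/E/V by a straight per-event-time loop.
oracle_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chi2 <- if (v == 0) 0 else (o1 - e1)^2 / v
  list(o1 = o1, e1 = e1, v = v, chi2 = chi2)
}

# Kaplan-Meier by an explicit product-limit loop.
oracle_km <- function(time, event) {
  s <- 1
  out <- numeric(0)
  times <- sort(unique(time))
  for (t in times) {
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_at_risk)
    out <- c(out, s)
  }
  data.frame(time = times, surv = out)
}

# Upper-tail hypergeometric by explicit combinatorial sum.
oracle_hyper_tail <- function(k, n_geneset, n_universe, n_query) {
  j <- k:min(n_geneset, n_query)
  sum(choose(n_geneset, j) * choose(n_universe - n_geneset, n_query - j)) /
    choose(n_universe, n_query)
}

# Straight-loop NB sampler with the same mean-dispersion parameterization
# (gamma-Poisson mixture drawn one value at a time).
oracle_nb_sample <- function(n, mu, phi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    lambda <- stats::rgamma(1, shape = 1 / phi, rate = 1 / (phi * mu))
    out[i] <- stats::rpois(1, lambda)
  }
  out
}
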