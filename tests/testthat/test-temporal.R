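STAGES <- c("naive", "initiation", "expansion", "end")

# hand-built tensor slice: mean matrix rows = populations, cols = stages;
# detection follows expression (1 where expressed, ambient 0.02 elsewhere)
toy_tensor <- function(gene, means, detection = NULL) {
  pops <- rownames(means)
  det <- detection %||% ifelse(means > 0.5, 1, 0.02)
  out <- tibble::tibble(
    gene = gene,
    population = rep(pops, times = ncol(means)),
    stage = factor(rep(STAGES, each = nrow(means)), levels = STAGES,
                   ordered = TRUE),
    mean_expr = as.vector(means),
    detection = as.vector(det)
  )
  class(out) <- c("stage_tensor", class(out))
  out
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("stage tensor matches hand-computed group means", {
  counts <- rbind(
    g1 = c(4, 4, 0, 0, 2, 2, 2, 2, 1, 1, 3, 3),
    g2 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  colnames(counts) <- paste0("c", 1:12)
  meta <- tibble::tibble(
    cell_id = paste0("c", 1:12),
    population = rep(c("P", "Q"), times = 6),
    stage = rep(STAGES, each = 3)
  )
  tens <- stage_tensor(counts, meta)
  norm <- normalize_cells(counts)
  # independent aggregation loop
  for (i in seq_len(nrow(tens))) {
    sel <- meta$population == tens$population[i] & meta$stage == tens$stage[i]
    expect_equal(tens$mean_expr[i], mean(norm[tens$gene[i], sel]))
    expect_equal(tens$detection[i], mean(counts[tens$gene[i], sel] > 0))
  }
  # all-zero gene: zero slice, zero detection
  expect_true(all(tens$mean_expr[tens$gene == "g2"] == 0))
  expect_true(all(tens$detection[tens$gene == "g2"] == 0))

  keep <- meta$stage != "end"
  expect_error(stage_tensor(counts[, keep], meta[keep, ]), "end")
})

test_that("the four planted templates classify to their classes", {
  mu <- 3
  bg <- 0.01
  lost <- toy_tensor("g", rbind(A = c(mu, mu, mu, bg), B = rep(bg, 4)))
  expect_equal(classify_trajectory(lost, "g"), "lost")

  transient <- toy_tensor("g", rbind(A = c(bg, mu, mu, bg), B = rep(bg, 4)))
  expect_equal(classify_trajectory(transient, "g"), "transient")

  shift <- toy_tensor("g", rbind(A = c(mu, mu, bg, bg), B = c(bg, bg, mu, mu)))
  expect_equal(classify_trajectory(shift, "g"), "population_shift")

  steady <- toy_tensor("g", rbind(A = rep(mu, 4), B = rep(bg, 4)))
  expect_equal(classify_trajectory(steady, "g"), "steady")

  # steady with a wildly varying trajectory fails the CV gate
  wobble <- toy_tensor("g", rbind(A = c(10, 1, 10, 1), B = rep(bg, 4)))
  expect_equal(classify_trajectory(wobble, "g"), "unclassified")

  expect_error(classify_trajectory(steady, "missing"), "missing")
})

test_that("classification is exhaustive, single-labelled and permutation-stable", {
  withr::with_seed(41, {
    for (i in 1:50) {
      means <- matrix(stats::runif(12, 0, 4), nrow = 3,
                      dimnames = list(c("A", "B", "C"), NULL))
      tens <- toy_tensor("g", means)
      cl <- classify_trajectory(tens, "g")
      expect_true(cl %in% c("steady", "lost", "transient", "population_shift",
                            "unclassified"))
      # permuting the population row order never changes the label
      perm <- sample(3)
      tens_p <- toy_tensor("g", means[perm, , drop = FALSE])
      expect_equal(classify_trajectory(tens_p, "g"), cl)
    }
  })
})

test_that("trajectory clustering groups by shape, not scale", {
  base <- rbind(A1 = c(1, 2, 3, 4), A2 = c(2, 4, 6, 8),     # same shape
                B1 = c(4, 3, 2, 1),                          # negation
                F1 = c(2, 2, 2, 2))                          # flat
  tens <- tibble::tibble(
    gene = rep(rownames(base), each = 4),
    population = "P",
    stage = factor(rep(STAGES, times = 4), levels = STAGES, ordered = TRUE),
    mean_expr = as.vector(t(base)),
    detection = 1
  )
  cl <- cluster_trajectories(tens, "P", k = 2)
  cls <- cl$clusters
  expect_equal(cls$cluster[cls$gene == "A1"], cls$cluster[cls$gene == "A2"])
  expect_false(cls$cluster[cls$gene == "A1"] == cls$cluster[cls$gene == "B1"])
  expect_equal(cls$cluster[cls$gene == "F1"], 0L)
  trends <- unique(cl$consensus[, c("cluster", "trend")])
  expect_setequal(trends$trend, c("increasing", "decreasing"))

  # affine invariance: a * traj + b preserves the clustering
  shifted <- dplyr::mutate(tens, mean_expr = 3 * mean_expr + 7)
  cl2 <- cluster_trajectories(shifted, "P", k = 2)
  expect_identical(cl$clusters, cl2$clusters)
})

test_that("clusters recover planted trajectory templates", {
  templates <- list(c(0, 1, 2, 3), c(3, 2, 1, 0), c(0, 3, 3, 0))
  ari <- numeric(50)
  withr::with_seed(43, {
    for (r in 1:50) {
      lab <- rep(1:3, length.out = 40)
      traj <- t(vapply(lab, function(k) {
        templates[[k]] + stats::rnorm(4, 0, 0.3)
      }, numeric(4)))
      tens <- tibble::tibble(
        gene = rep(sprintf("g%02d", 1:40), each = 4),
        population = "P",
        stage = factor(rep(STAGES, times = 40), levels = STAGES,
                       ordered = TRUE),
        mean_expr = as.vector(t(traj)),
        detection = 1
      )
      cl <- cluster_trajectories(tens, "P", k = 3)
      got <- cl$clusters$cluster[match(sprintf("g%02d", 1:40), cl$clusters$gene)]
      ari[r] <- mclust::adjustedRandIndex(lab, got)
    }
  })
  expect_gte(mean(ari), 0.9)
})

test_that("population proportions carry honest monotone trend tags", {
  meta <- tibble::tibble(
    cell_id = as.character(1:200),
    population = c(rep("up", 40), rep("flat", 160)),
    stage = c(rep(STAGES, times = c(4, 8, 12, 16)),
              rep(STAGES, each = 40))
  )
  props <- population_proportions(meta)
  up <- props[props$population == "up", ]
  expect_equal(unique(up$trend), "increasing")

  flat_meta <- tibble::tibble(
    cell_id = as.character(1:80),
    population = rep(c("x", "y"), each = 40),
    stage = rep(rep(STAGES, each = 10), times = 2)
  )
  fp <- population_proportions(flat_meta)
  expect_true(all(fp$trend == "none"))
})

test_that("synthetic default drift directions are recovered from cell labels", {
  cfg <- synth_config(seed = 44, n_cells_per_stage = 2000)
  niche <- simulate_niche(cfg)
  props <- population_proportions(niche$meta)
  tags <- unique(props[, c("population", "trend")])
  truth <- niche$truth$proportion_trends
  expect_equal(tags$trend[match(truth$population, tags$population)],
               truth$trend)
})
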