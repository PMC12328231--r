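test_that("identical config and seed give identical outputs from every generator", {
  cfg <- synth_config(seed = 9, n_genes = 300, n_cells_per_stage = 100)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$bulk$datasets$bcCML$counts, b$bulk$datasets$bcCML$counts)
  expect_identical(a$bulk$datasets$AML$counts, b$bulk$datasets$AML$counts)
  expect_identical(a$screen$table, b$screen$table)
  expect_identical(a$niche$counts, b$niche$counts)
  expect_identical(a$niche$meta, b$niche$meta)
  expect_identical(a$survival$table, b$survival$table)
  expect_identical(a$lr$table, b$lr$table)
  expect_identical(a$dose, b$dose)
  expect_identical(a$truth, b$truth)
})

test_that("bulk counts match the NB parameterization against a straight-loop sampler", {
  cfg <- synth_config(seed = 2, n_genes = 300, n_samples_per_group = 50,
                      mean_range = c(100, 100))
  bulk <- simulate_bulk(cfg)
  ds <- bulk$datasets$bcCML
  disease_cols <- ds$groups == "disease"
  x <- ds$counts["REC01", disease_cols]  # planted +2: mean should be 400

  withr::with_seed(99, {
    ref <- oracle_nb_sample(2000, mu = 400, phi = cfg$nb_dispersion)
  })
  se <- sqrt(stats::var(x) / length(x) + stats::var(ref) / length(ref))
  expect_lt(abs(mean(x) - mean(ref)), 3 * se)

  # neutral gene around the baseline mean
  y <- ds$counts["G0001", disease_cols]
  se_y <- sqrt(stats::var(y) / length(y))
  expect_lt(abs(mean(y) - 100), 4 * se_y)
})

test_that("a fully null bulk config yields nominal downstream type-I error", {
  null_rec <- tibble::tibble(gene = sprintf("REC%02d", 1:8),
                             disease = c(rep("both", 4), rep("AML", 2),
                                         rep("bcCML", 2)),
                             lfc = 0)
  cfg <- synth_config(seed = 5, n_genes = 2000, planted_receptors = null_rec,
                      planted_lfc = 0)
  bulk <- simulate_bulk(cfg)
  ds <- bulk$datasets$AML
  de <- de_test(ds$counts, ds$groups, control = ds$control)
  rate <- mean(de$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("screen generator honours zero-noise effects and the null call rate", {
  cfg0 <- synth_config(seed = 3, n_genes = 300, guide_sd = 0)
  scr0 <- simulate_screen(cfg0)
  g <- scr0$table[scr0$table$gene == "REC01", ]
  expect_equal(g$log2fc, rep(-1.5, cfg0$n_guides_per_gene))
  expect_true("REC01" %in% screen_dropouts(scr0$table))

  # neutral genome with wide guide noise: dropout call rate must match the
  # median-rule null rate estimated by direct Monte-Carlo simulation
  cfg <- synth_config(seed = 4, n_genes = 2000, guide_sd = 1,
                      dropout_genes = tibble::tibble(gene = "REC01", effect = -1))
  scr <- simulate_screen(cfg)
  neutral <- scr$table[scr$table$gene != "REC01", ]
  called <- screen_dropouts(neutral)
  rate <- length(called) / length(unique(neutral$gene))

  withr::with_seed(123, {
    sims <- replicate(20000, stats::median(stats::rnorm(4, 0, 1)) <= -1)
  })
  p0 <- mean(sims)
  se <- sqrt(p0 * (1 - p0) / length(unique(neutral$gene)) +
               p0 * (1 - p0) / 20000)
  expect_lt(abs(rate - p0), 3 * se + 1e-12)
})

test_that("niche populations follow the planted multinomial proportions", {
  props <- tibble::tibble(
    population = rep(c("P", "Q"), each = 4),
    stage = rep(c("naive", "initiation", "expansion", "end"), 2),
    proportion = c(0.1, 0.2, 0.3, 0.4, 0.9, 0.8, 0.7, 0.6)
  )
  lig <- tibble::tibble(gene = "LIG01", population = "P", class = "steady",
                        mu = 5, shift_population = NA, shift_stage = NA)
  lr <- tibble::tibble(ligand = "LIG01", receptor = "REC01", planted = TRUE)
  cfg <- synth_config(seed = 6, population_proportions = props,
                      planted_ligands = lig, lr_pairs = lr,
                      nonenriched_receptors = character(),
                      n_cells_per_stage = 10000,
                      n_niche_background_genes = 5)
  niche <- simulate_niche(cfg)
  obs <- table(niche$meta$stage, niche$meta$population)
  targets <- c(naive = 0.1, initiation = 0.2, expansion = 0.3, end = 0.4)
  for (s in names(targets)) {
    p <- targets[[s]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(obs[s, "P"] / 10000 - p), 3 * se)
  }
})

test_that("planted temporal templates shape the niche expression means", {
  cfg <- synth_config(seed = 7)
  niche <- simulate_niche(cfg)
  tens <- stage_tensor(niche$counts, niche$meta)

  # LIG02 planted as lost in MSC: expression collapses to background at end
  lost <- tens[tens$gene == "LIG02" & tens$population == "MSC", ]
  expect_gt(lost$detection[lost$stage == "naive"], 0.9)
  expect_lt(lost$detection[lost$stage == "end"], 0.1)
  expect_lt(lost$mean_expr[lost$stage == "end"],
            0.05 * lost$mean_expr[lost$stage == "naive"])

  # LIG03 planted as transient in osteo: argmax stage is interior
  tr <- tens[tens$gene == "LIG03" & tens$population == "osteo", ]
  expect_true(which.max(tr$mean_expr) %in% c(2, 3))
})

test_that("the interaction-table generator respects planted and forbidden pairs", {
  cfg <- synth_config(seed = 8)
  lr <- simulate_lr_table(cfg)
  expect_equal(sum(lr$table$receptor %in% cfg$ligandless_receptors), 0)
  one <- lr$table[lr$table$ligand == "LIG01" & lr$table$receptor == "REC01", ]
  expect_equal(nrow(one), 1)
  expect_equal(one$source, "planted")
  expect_equal(sum(lr$table$source == "decoy"), cfg$n_decoy_pairs)
})

test_that("survival generator is prognostic for planted beta and null otherwise", {
  hits <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    cfg <- synth_config(
      seed = 3000 + r,
      survival = list(genes = "REC01", betas = c(REC01 = 1),
                      n_patients = 400, censor_max = 1e9)
    )
    sv <- simulate_survival_data(cfg)
    d <- sv$table
    s <- stratified_survival(d)
    hits <- hits + (s$hr > 1)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("configuration errors are caught", {
  expect_error(synth_config(nb_dispersion = 0), "positive")
  expect_error(synth_config(n_samples_per_group = 1), "at least 2")
  expect_error(synth_config(n_genes = 10), "too small")
  expect_error(
    synth_config(dropout_genes = tibble::tibble(gene = "REC01", effect = -0.5)),
    "at most -1"
  )
  bad_props <- tibble::tibble(
    population = rep(c("P", "Q"), each = 4),
    stage = rep(c("naive", "initiation", "expansion", "end"), 2),
    proportion = c(0.2, 0.2, 0.3, 0.4, 0.9, 0.8, 0.7, 0.6)
  )
  expect_error(synth_config(population_proportions = bad_props), "sum to 1")
  bad_lig <- tibble::tibble(gene = "LIG01", population = "MSC",
                            class = "oscillating", mu = 5,
                            shift_population = NA, shift_stage = NA)
  expect_error(synth_config(planted_ligands = bad_lig), "unknown temporal class")
  bad_lr <- tibble::tibble(ligand = "LIG01", receptor = "RECX1", planted = TRUE)
  lig1 <- tibble::tibble(gene = "LIG01", population = "MSC", class = "steady",
                         mu = 5, shift_population = NA, shift_stage = NA)
  expect_error(synth_config(planted_ligands = lig1, lr_pairs = bad_lr),
               "ligandless")
})
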