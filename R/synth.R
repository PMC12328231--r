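# Seeded generators for every pipeline input, with a ground-truth ledger.
# Each generator derives its RNG stream from the root seed plus a fixed
# per-dataset offset, so datasets are independently reproducible.

OFFSET_BULK <- 11L
OFFSET_SCREEN <- 12L
OFFSET_NICHE <- 13L
OFFSET_SURVIVAL <- 14L
OFFSET_LR <- 15L
OFFSET_SYNERGY <- 16L

# Genes planted as upregulated (disease vs control) in a given disease,
# with their planted effects. Ligandless / non-enriched / blacklisted genes
# are planted in both diseases at the default effect.
planted_bulk_effects <- function(config, disease) {
  pr <- config$planted_receptors
  keep <- pr$disease %in% c("both", disease)
  extra <- c(config$ligandless_receptors, config$nonenriched_receptors,
             config$blacklist_genes)
  tibble::tibble(
    gene = c(pr$gene[keep], extra),
    lfc = c(pr$lfc[keep], rep(config$planted_lfc, length(extra)))
  )
}

#' Simulate two-disease bulk RNA-seq counts
#'
#' Draws gene-by-sample negative-binomial counts for two disease datasets
#' (bcCML and AML), each with its own control group of the same design.
#' Gene baseline means are log-uniform over `mean_range`; a planted gene's
#' disease-group mean is multiplied by `2^lfc`. Variance follows the
#' mean-dispersion form `Var = mu + mu^2 * phi`.
#'
#' @param config A [synth_config()].
#' @return List with `datasets` (per disease: `counts` matrix, `groups`,
#'   `control`) and `truth` (planted per-gene effects per dataset).
#' @export
simulate_bulk <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples_per_group
  phi <- config$nb_dispersion
  genes <- config$universe

  with_dataset_seed(config$seed, OFFSET_BULK, {
    datasets <- list()
    truth <- list()
    for (disease in c("bcCML", "AML")) {
      base_mu <- exp(stats::runif(length(genes),
                                  log(config$mean_range[1]),
                                  log(config$mean_range[2])))
      names(base_mu) <- genes
      eff <- planted_bulk_effects(config, disease)
      missing <- setdiff(eff$gene, genes)
      if (length(missing) > 0) {
        stop("planted gene not in universe: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      dis_mu <- base_mu
      dis_mu[eff$gene] <- dis_mu[eff$gene] * 2^eff$lfc

      draw <- function(mu_vec) {
        matrix(stats::rnbinom(length(mu_vec) * n, size = 1 / phi,
                              mu = rep(mu_vec, times = n)),
               nrow = length(mu_vec))
      }
      ctrl <- draw(base_mu)
      dis <- draw(dis_mu)
      counts <- cbind(ctrl, dis)
      storage.mode(counts) <- "integer"
      rownames(counts) <- genes
      colnames(counts) <- c(sprintf("%s_control_%02d", disease, seq_len(n)),
                            sprintf("%s_disease_%02d", disease, seq_len(n)))
      datasets[[disease]] <- list(
        counts = counts,
        groups = rep(c("control", "disease"), each = n),
        control = "control"
      )
      truth[[disease]] <- tibble::tibble(dataset = disease,
                                         gene = eff$gene, lfc = eff$lfc)
    }
    list(datasets = datasets, truth = dplyr::bind_rows(truth))
  })
}

#' Simulate a CRISPR dropout screen
#'
#' Per-guide log2 abundance fold-changes drawn as
#' `Normal(gene effect, guide_sd)`; genes without a planted dropout effect are
#' neutral (effect 0). All genes in the bulk universe are covered.
#'
#' @param config A [synth_config()].
#' @return List with `table` (tibble `gene`, `guide`, `log2fc`) and `truth`
#'   (per-gene planted effects).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- config$universe
  k <- config$n_guides_per_gene
  effect <- stats::setNames(rep(0, length(genes)), genes)
  effect[config$dropout_genes$gene] <- config$dropout_genes$effect

  with_dataset_seed(config$seed, OFFSET_SCREEN, {
    tab <- tibble::tibble(
      gene = rep(genes, each = k),
      guide = paste0(rep(genes, each = k), "_g", rep(seq_len(k), times = length(genes))),
      log2fc = stats::rnorm(length(genes) * k,
                            mean = rep(effect, each = k),
                            sd = config$guide_sd)
    )
    list(table = tab,
         truth = tibble::tibble(gene = genes, effect = unname(effect)))
  })
}

# Per-stage mean template for one planted ligand in one population.
# Classes: steady (mu, mu, mu, mu); lost (mu, mu, mu, bg); transient
# (bg, mu, mu, bg); population_shift moves expression to shift_population
# from shift_stage onward. Background level stands in for zero so that
# detection stays below the expression threshold.
ligand_mean <- function(row, population, stage_idx, bg) {
  mu <- row$mu
  in_home <- population == row$population
  switch(row$class,
    steady = if (in_home) mu else bg,
    lost = if (in_home && stage_idx <= 3) mu else bg,
    transient = if (in_home && stage_idx %in% c(2, 3)) mu else bg,
    population_shift = {
      before <- stage_idx < row$shift_stage
      if ((before && in_home) ||
          (!before && population == row$shift_population)) mu else bg
    },
    stop("unknown temporal class: ", row$class, call. = FALSE)
  )
}

#' Simulate stage-labelled stromal single-cell counts
#'
#' Cells are assigned to populations multinomially per stage using the
#' configured proportion drifts, and counts are Poisson around
#' population-by-stage gene means. Planted ligands follow their temporal-class
#' templates; decoy ligands sit at background; unrelated stromal genes get
#' constant log-uniform means.
#'
#' @param config A [synth_config()].
#' @return List with `counts` (genes x cells), `meta` (tibble `cell_id`,
#'   `population`, `stage`), and `truth` (planted ligand table and the
#'   population proportion targets).
#' @export
simulate_niche <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  stages <- config$stages
  props <- config$population_proportions
  pops <- unique(props$population)
  bg <- config$ligand_background

  lig <- config$planted_ligands
  decoys <- sprintf("DLIG%02d", seq_len(12))
  nbg <- config$n_niche_background_genes
  bg_genes <- sprintf("NCH%02d", seq_len(nbg))
  genes <- c(lig$gene, decoys, bg_genes)

  with_dataset_seed(config$seed, OFFSET_NICHE, {
    bg_mu <- exp(stats::runif(nbg, log(config$niche_background_range[1]),
                              log(config$niche_background_range[2])))
    # mean array [gene, population, stage]
    mu_arr <- array(bg, dim = c(length(genes), length(pops), length(stages)),
                    dimnames = list(genes, pops, stages))
    mu_arr[bg_genes, , ] <- rep(bg_mu, times = length(pops) * length(stages))
    for (i in seq_len(nrow(lig))) {
      row <- lig[i, ]
      for (p in seq_along(pops)) {
        for (s in seq_along(stages)) {
          mu_arr[row$gene, p, s] <- ligand_mean(row, pops[p], s, bg)
        }
      }
    }

    meta <- list()
    blocks <- list()
    for (s in seq_along(stages)) {
      pr <- vapply(pops, function(p) {
        props$proportion[props$population == p & props$stage == stages[s]]
      }, numeric(1))
      n_cells <- config$n_cells_per_stage
      pop_n <- as.vector(stats::rmultinom(1, n_cells, pr))
      pop_lab <- rep(pops, pop_n)
      mu_cells <- mu_arr[, match(pop_lab, pops), s]
      cnt <- matrix(stats::rpois(length(mu_cells), mu_cells), nrow = length(genes))
      storage.mode(cnt) <- "integer"
      rownames(cnt) <- genes
      ids <- sprintf("cell_%s_%04d", stages[s], seq_len(n_cells))
      colnames(cnt) <- ids
      blocks[[s]] <- cnt
      meta[[s]] <- tibble::tibble(cell_id = ids, population = pop_lab,
                                  stage = stages[s])
    }
    counts <- do.call(cbind, blocks)
    meta <- dplyr::bind_rows(meta)

    drift <- props |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(
        rho = stats::cor(seq_along(.data$proportion), .data$proportion,
                         method = "spearman"),
        .groups = "drop"
      ) |>
      dplyr::mutate(trend = dplyr::case_when(
        .data$rho >= 0.8 ~ "increasing",
        .data$rho <= -0.8 ~ "decreasing",
        TRUE ~ "none"
      ))
    list(counts = counts, meta = meta,
         truth = list(ligands = lig, proportion_targets = props,
                      proportion_trends = drift))
  })
}

#' Simulate per-receptor patient survival tables
#'
#' For each gene in the survival panel: expression is Normal, event times are
#' exponential with rate `h0 * exp(beta * (expression - expr_mean))`, and
#' censoring is uniform on `(0, censor_max)`.
#'
#' @param config A [synth_config()].
#' @return List with `table` (tibble `gene`, `id`, `time`, `event`,
#'   `expression`) and `truth` (per-gene beta).
#' @export
simulate_survival_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sv <- config$survival
  betas <- stats::setNames(rep(0, length(sv$genes)), sv$genes)
  known <- intersect(names(sv$betas), sv$genes)
  betas[known] <- sv$betas[known]

  with_dataset_seed(config$seed, OFFSET_SURVIVAL, {
    rows <- lapply(sv$genes, function(g) {
      z <- stats::rnorm(sv$n_patients, sv$expr_mean, sv$expr_sd)
      rate <- sv$h0 * exp(betas[[g]] * (z - sv$expr_mean))
      t_event <- stats::rexp(sv$n_patients, rate)
      t_cens <- stats::runif(sv$n_patients, 0, sv$censor_max)
      tibble::tibble(
        gene = g,
        id = sprintf("%s_pt%03d", g, seq_len(sv$n_patients)),
        time = pmin(t_event, t_cens),
        event = as.integer(t_event <= t_cens),
        expression = z
      )
    })
    list(table = dplyr::bind_rows(rows),
         truth = tibble::tibble(gene = sv$genes, beta = unname(betas)))
  })
}

#' Simulate the ligand-receptor interaction table
#'
#' Emits all configured (planted and curated) pairs plus `n_decoy_pairs`
#' random decoy rows among decoy gene names. No row ever references a
#' ligandless receptor.
#'
#' @param config A [synth_config()].
#' @return List with `table` (tibble `ligand`, `receptor`, `source`) and
#'   `truth` (the planted pair flags).
#' @export
simulate_lr_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  base <- config$lr_pairs |>
    dplyr::mutate(source = ifelse(.data$planted, "planted", "curated")) |>
    dplyr::select("ligand", "receptor", "source")

  with_dataset_seed(config$seed, OFFSET_LR, {
    decoy_lig <- sprintf("DLIG%02d", 5:12)
    decoy_rec <- sprintf("DREC%02d", 1:10)
    grid <- expand.grid(ligand = decoy_lig, receptor = decoy_rec,
                        stringsAsFactors = FALSE)
    pick <- sample(nrow(grid), min(config$n_decoy_pairs, nrow(grid)))
    decoys <- tibble::tibble(ligand = grid$ligand[pick],
                             receptor = grid$receptor[pick],
                             source = "decoy")
    tab <- dplyr::bind_rows(base, decoys)
    if (length(intersect(config$ligandless_receptors, tab$receptor)) > 0) {
      stop("ligandless receptor collided with an interaction row", call. = FALSE)
    }
    list(table = tab, truth = config$lr_pairs)
  })
}

#' Simulate median-effect dose-response data
#'
#' Single-agent curves follow the median-effect equation
#' `fa / (1 - fa) = (D / Dm)^m`, optionally with Normal noise on the
#' `log10(fa/(1-fa))` scale. Combination rows are built on the configured
#' `fa_grid` with doses scaled so that the planted combination index equals
#' `interaction` at every fraction affected.
#'
#' @param config A [synth_config()].
#' @return List with `single` (tibble `drug`, `dose`, `fa`), `combo`
#'   (tibble `d1`, `d2`, `fa`), and `truth` (drug parameters and the planted
#'   interaction factor).
#' @export
simulate_dose_response <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sy <- config$synergy
  drugs <- sy$drugs

  with_dataset_seed(config$seed, OFFSET_SYNERGY, {
    single <- lapply(seq_len(nrow(drugs)), function(i) {
      d <- drugs$dm[i] * sy$dose_mult
      y <- drugs$m[i] * (log10(d) - log10(drugs$dm[i]))
      if (sy$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, sy$noise_sd)
      tibble::tibble(drug = drugs$drug[i], dose = d, fa = 10^y / (1 + 10^y))
    })
    dx <- function(i, fa) drugs$dm[i] * (fa / (1 - fa))^(1 / drugs$m[i])
    combo <- tibble::tibble(
      fa = sy$fa_grid,
      d1 = sy$interaction / 2 * dx(1, sy$fa_grid),
      d2 = sy$interaction / 2 * dx(2, sy$fa_grid)
    )[, c("d1", "d2", "fa")]
    list(single = dplyr::bind_rows(single), combo = combo,
         truth = list(drugs = drugs, interaction = sy$interaction))
  })
}

#' Run every generator and collect the truth ledger
#'
#' @param config A [synth_config()].
#' @return A `nm_study` list: `bulk`, `screen`, `niche`, `survival`, `lr`,
#'   `dose`, plus `truth` (the combined machine-readable ground-truth ledger)
#'   and the `config`.
#' @export
simulate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  bulk <- simulate_bulk(config)
  screen <- simulate_screen(config)
  niche <- simulate_niche(config)
  surv <- simulate_survival_data(config)
  lr <- simulate_lr_table(config)
  dose <- simulate_dose_response(config)
  structure(list(
    bulk = bulk, screen = screen, niche = niche,
    survival = surv, lr = lr, dose = dose,
    truth = list(
      bulk = bulk$truth, screen = screen$truth, ligands = niche$truth$ligands,
      proportion_trends = niche$truth$proportion_trends,
      survival = surv$truth, lr = lr$truth, dose = dose$truth
    ),
    config = config
  ), class = "nm_study")
}
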