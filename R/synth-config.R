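#' Configuration for the synthetic multi-omic study generator
#'
#' Builds and validates the configuration object consumed by the
#' `simulate_*()` generators. Defaults describe a compact study with planted
#' ground truth in every layer: negative-binomial bulk counts with upregulated
#' receptor genes in two diseases, per-guide CRISPR screen log fold-changes
#' with planted dropouts, a four-stage stromal single-cell dataset with
#' planted ligand trajectories and drifting population proportions, a
#' ligand-receptor table with planted axes, deliberately ligand-less
#' receptors, decoy pairs, per-receptor patient survival with
#' expression-dependent hazard, and median-effect dose-response curves.
#'
#' Planted genes by default:
#' * `REC01`-`REC08`: true receptors (upregulated + screen dropout + surface),
#'   4 shared between diseases, 2 AML-only, 2 bcCML-only; each paired to a
#'   planted ligand `LIG01`-`LIG08`.
#' * `RECX1`, `RECX2`: receptors with no ligand-receptor table entry.
#' * `RECY1`, `RECY2`: receptors whose only ligands are never enriched.
#' * `BLK01`-`BLK03`: surface-misannotated genes on the blacklist.
#' * `DRP01`-`DRP05`: screen dropouts that are not upregulated (decoys).
#'
#' @param seed Root seed; every generator derives its stream from it.
#' @param n_genes Bulk gene universe size (filler genes are `G0001`, ...).
#' @param n_samples_per_group Bulk samples per group and disease.
#' @param nb_dispersion Negative-binomial dispersion phi in
#'   `Var = mu + mu^2 * phi`.
#' @param mean_range Range of log-uniform baseline means for bulk genes.
#' @param planted_receptors Tibble `gene`, `disease` (`both`/`AML`/`bcCML`),
#'   `lfc` (planted log2 effect in the disease group).
#' @param planted_lfc Effect given to ligandless / non-enriched / blacklisted
#'   planted genes (all planted as `both`).
#' @param n_guides_per_gene,guide_sd CRISPR screen design: guides per gene and
#'   per-guide normal noise (log2 scale).
#' @param dropout_genes Tibble `gene`, `effect` with effects at most -1 (log2).
#' @param stages Ordered stage labels.
#' @param population_proportions Tibble `population`, `stage`, `proportion`;
#'   proportions must sum to 1 within each stage.
#' @param n_cells_per_stage Cells drawn per stage.
#' @param planted_ligands Tibble `gene`, `population`, `class`
#'   (`steady`/`lost`/`transient`/`population_shift`), `mu`, and for
#'   `population_shift` a `shift_population` and `shift_stage`.
#' @param ligand_background Mean count of a planted/decoy ligand outside its
#'   expressing (population, stage) cells.
#' @param n_niche_background_genes,niche_background_range Unrelated stromal
#'   genes and the log-uniform range of their mean counts.
#' @param lr_pairs Tibble `ligand`, `receptor`, `planted` (logical); every
#'   planted ligand must be paired to a planted receptor.
#' @param n_decoy_pairs Random decoy rows added by [simulate_lr_table()].
#' @param ligandless_receptors Receptors that must not appear in `lr_pairs`.
#' @param nonenriched_receptors Receptors whose ligands are never enriched.
#' @param blacklist_genes Misannotated surface genes.
#' @param atlas_genes Surface-atlas annotation (includes the blacklist and a
#'   slice of filler genes as surface decoys).
#' @param survival List: `genes` (panel), `betas` (named log-hazard
#'   coefficients per unit expression; missing genes get 0), `n_patients`,
#'   `h0` baseline hazard, `expr_mean`, `expr_sd`, `censor_max`.
#' @param synergy List: `drugs` tibble (`drug`, `m`, `dm`), `dose_mult` dose
#'   grid as multiples of Dm, `fa_grid` combination fractions affected,
#'   `interaction` planted combination index, `noise_sd` logit10-scale noise.
#' @return A validated `synth_config` list; `$universe` holds the bulk gene
#'   universe.
#' @export
synth_config <- function(seed = 1,
                         n_genes = 2000,
                         n_samples_per_group = 10,
                         nb_dispersion = 0.1,
                         mean_range = c(5, 500),
                         planted_receptors = NULL,
                         planted_lfc = 2,
                         n_guides_per_gene = 4,
                         guide_sd = 0.3,
                         dropout_genes = NULL,
                         stages = c("naive", "initiation", "expansion", "end"),
                         population_proportions = NULL,
                         n_cells_per_stage = 400,
                         planted_ligands = NULL,
                         ligand_background = 0.02,
                         n_niche_background_genes = 40,
                         niche_background_range = c(0.1, 2),
                         lr_pairs = NULL,
                         n_decoy_pairs = 20,
                         ligandless_receptors = c("RECX1", "RECX2"),
                         nonenriched_receptors = c("RECY1", "RECY2"),
                         blacklist_genes = c("BLK01", "BLK02", "BLK03"),
                         atlas_genes = NULL,
                         survival = list(),
                         synergy = list()) {
  planted_receptors <- planted_receptors %||% tibble::tibble(
    gene = sprintf("REC%02d", 1:8),
    disease = c(rep("both", 4), rep("AML", 2), rep("bcCML", 2)),
    lfc = rep(2, 8)
  )
  if (!all(planted_receptors$disease %in% c("both", "AML", "bcCML"))) {
    stop("planted receptor disease must be one of both/AML/bcCML", call. = FALSE)
  }

  planted_extra <- c(ligandless_receptors, nonenriched_receptors, blacklist_genes)
  dropout_default <- tibble::tibble(
    gene = c(planted_receptors$gene, planted_extra, sprintf("DRP%02d", 1:5)),
    effect = -1.5
  )
  dropout_genes <- dropout_genes %||% dropout_default
  if (any(dropout_genes$effect > -1)) {
    stop("planted dropout effects must be at most -1 (log2)", call. = FALSE)
  }

  if (length(stages) != 4) stop("exactly four ordered stages are required", call. = FALSE)

  population_proportions <- population_proportions %||% tibble::tibble(
    population = rep(c("MSC", "osteo", "arteriolar_EC", "sinusoidal_EC"), each = 4),
    stage = rep(stages, times = 4),
    proportion = c(0.15, 0.20, 0.25, 0.30,
                   0.10, 0.13, 0.17, 0.20,
                   0.10, 0.13, 0.17, 0.20,
                   0.65, 0.54, 0.41, 0.30)
  )
  sums <- tapply(population_proportions$proportion, population_proportions$stage, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("population proportions must sum to 1 within each stage", call. = FALSE)
  }
  if (!all(population_proportions$stage %in% stages)) {
    stop("population proportions reference unknown stages", call. = FALSE)
  }

  pops <- unique(population_proportions$population)
  planted_ligands <- planted_ligands %||% tibble::tibble(
    gene = sprintf("LIG%02d", 1:8),
    population = c("MSC", "MSC", "osteo", "MSC",
                   "arteriolar_EC", "osteo", "sinusoidal_EC", "MSC"),
    class = c("steady", "lost", "transient", "population_shift",
              "steady", "steady", "lost", "transient"),
    mu = 5,
    shift_population = c(NA, NA, NA, "osteo", NA, NA, NA, NA),
    shift_stage = c(NA, NA, NA, 3L, NA, NA, NA, NA)
  )
  bad_class <- setdiff(planted_ligands$class,
                       c("steady", "lost", "transient", "population_shift"))
  if (length(bad_class) > 0) {
    stop("unknown temporal class: ", paste(bad_class, collapse = ", "), call. = FALSE)
  }
  if (!all(planted_ligands$population %in% pops)) {
    stop("planted ligand population not in population table", call. = FALSE)
  }
  shift <- planted_ligands$class == "population_shift"
  if (any(shift & (is.na(planted_ligands$shift_population) |
                     is.na(planted_ligands$shift_stage)))) {
    stop("population_shift ligands need shift_population and shift_stage", call. = FALSE)
  }

  lr_pairs <- lr_pairs %||% dplyr::bind_rows(
    tibble::tibble(ligand = planted_ligands$gene,
                   receptor = planted_receptors$gene[seq_len(nrow(planted_ligands))],
                   planted = TRUE),
    tibble::tibble(ligand = rep(sprintf("DLIG%02d", 1:4), times = 1),
                   receptor = rep(nonenriched_receptors, each = 2),
                   planted = FALSE)
  )
  if (length(intersect(ligandless_receptors, lr_pairs$receptor)) > 0) {
    stop("ligandless receptors must not appear in lr_pairs", call. = FALSE)
  }
  planted_lig_ok <- planted_ligands$gene %in%
    lr_pairs$ligand[lr_pairs$planted & lr_pairs$receptor %in% planted_receptors$gene]
  if (!all(planted_lig_ok)) {
    stop("every planted ligand must be paired to a planted receptor in lr_pairs",
         call. = FALSE)
  }

  n_planted_bulk <- nrow(planted_receptors) + length(planted_extra) +
    nrow(dropout_genes)
  if (n_genes < n_planted_bulk + 100) {
    stop("n_genes too small for the planted genes", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (n_samples_per_group < 2) stop("need at least 2 samples per group", call. = FALSE)
  if (n_guides_per_gene < 1) stop("need at least 1 guide per gene", call. = FALSE)

  special <- unique(c(planted_receptors$gene, planted_extra, dropout_genes$gene))
  fillers <- sprintf("G%04d", seq_len(n_genes - length(special)))
  universe <- c(special, fillers)

  atlas_genes <- atlas_genes %||%
    c(planted_receptors$gene, planted_extra, fillers[1:100])

  survival <- utils::modifyList(list(
    genes = c(planted_receptors$gene, ligandless_receptors, nonenriched_receptors),
    betas = c(REC01 = 1, REC02 = 1),
    n_patients = 161,
    h0 = 0.08,
    expr_mean = 10,
    expr_sd = 1,
    censor_max = 30
  ), survival)
  if (survival$censor_max <= 0) stop("censoring window must be positive", call. = FALSE)
  if (!all(is.finite(survival$betas))) stop("survival betas must be finite", call. = FALSE)

  synergy <- utils::modifyList(list(
    drugs = tibble::tibble(drug = c("GES", "venetoclax"), m = c(2, 1.5), dm = c(1, 10)),
    dose_mult = c(0.25, 0.5, 1, 2, 4),
    fa_grid = seq(0.2, 0.8, by = 0.1),
    interaction = 0.5,
    noise_sd = 0
  ), synergy)

  structure(list(
    seed = as.integer(seed),
    n_genes = n_genes,
    n_samples_per_group = n_samples_per_group,
    nb_dispersion = nb_dispersion,
    mean_range = mean_range,
    planted_receptors = planted_receptors,
    planted_lfc = planted_lfc,
    n_guides_per_gene = n_guides_per_gene,
    guide_sd = guide_sd,
    dropout_genes = dropout_genes,
    stages = stages,
    population_proportions = population_proportions,
    n_cells_per_stage = n_cells_per_stage,
    planted_ligands = planted_ligands,
    ligand_background = ligand_background,
    n_niche_background_genes = n_niche_background_genes,
    niche_background_range = niche_background_range,
    lr_pairs = lr_pairs,
    n_decoy_pairs = n_decoy_pairs,
    ligandless_receptors = ligandless_receptors,
    nonenriched_receptors = nonenriched_receptors,
    blacklist_genes = blacklist_genes,
    atlas_genes = atlas_genes,
    survival = survival,
    synergy = synergy,
    universe = universe
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed", x$seed, "|", x$n_genes, "bulk genes,",
      x$n_samples_per_group, "samples/group |",
      nrow(x$planted_receptors), "planted receptors,",
      nrow(x$planted_ligands), "planted ligands |",
      x$n_cells_per_stage, "cells/stage\n")
  invisible(x)
}
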