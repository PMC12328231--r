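# End-to-end orchestration: differential expression for both diseases, the
# receptor cascade, ligand enrichment, interactome assembly, temporal
# classification, proportion dynamics and prognostic prioritization.

#' Pipeline thresholds
#'
#' @param alpha Adjusted-p threshold used by the upregulation filter, ligand
#'   calls and prognostic flag.
#' @param fold Screen dropout fold threshold.
#' @param min_lfc,min_pct Ligand-call effect-size and detection gates.
#' @param lfc_cap Export cap on ligand log2 fold-changes.
#' @param theta_expr,theta_cv Temporal classification thresholds.
#' @param min_cells Minimum population size for marker testing.
#' @param prognosis_adjust Multiplicity handling for the prognostic flag.
#' @param prognosis_scope Test the post-blacklist panel (default) or only
#'   cascade survivors.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(alpha = 0.05, fold = 2, min_lfc = 0,
                            min_pct = 0.1, lfc_cap = 5, theta_expr = 0.1,
                            theta_cv = 0.5, min_cells = 10,
                            prognosis_adjust = c("BH", "none"),
                            prognosis_scope = c("post_blacklist", "survivors")) {
  stopifnot(alpha > 0, alpha < 1, fold > 1, min_pct >= 0, min_pct <= 1)
  list(alpha = alpha, fold = fold, min_lfc = min_lfc, min_pct = min_pct,
       lfc_cap = lfc_cap, theta_expr = theta_expr, theta_cv = theta_cv,
       min_cells = min_cells,
       prognosis_adjust = match.arg(prognosis_adjust),
       prognosis_scope = match.arg(prognosis_scope))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: differential expression for each disease against its
#' controls, upregulation / surface / screen-dropout / blacklist filtering
#' into the receptor ledger, per-population ligand enrichment, ligand-based
#' exclusion, interactome assembly, stage-tensor construction with temporal
#' classification, population-proportion dynamics, and survival-based
#' receptor prioritization. Optionally writes the ledger and edge TSVs plus
#' a JSON report.
#'
#' @param study An `nm_study` from [simulate_study()], or a directory path
#'   written by [write_simulation()] (missing files fail before any
#'   computation).
#' @param params [pipeline_params()].
#' @param out Optional output directory for `ledger.tsv`, `edges.tsv`,
#'   `report.json`.
#' @return A `pipeline_report` list: `de`, `ledger`, `counts`, `markers`,
#'   `calls`, `edges`, `tensor`, `classes`, `proportions`, `prognosis`,
#'   `provenance`.
#' @export
run_all <- function(study, params = pipeline_params(), out = NULL) {
  if (is.character(study)) study <- read_simulation(study)
  stopifnot(inherits(study, "nm_study"))
  cfg <- study$config
  atlas <- if (!is.null(cfg)) cfg$atlas_genes else study$meta$atlas
  blacklist <- if (!is.null(cfg)) cfg$blacklist_genes else study$meta$blacklist
  stages <- if (!is.null(cfg)) cfg$stages else study$meta$stages
  seed <- if (!is.null(cfg)) cfg$seed else study$meta$seed

  stage_fail <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  de <- stage_fail("de_test", lapply(study$bulk$datasets, function(ds) {
    de_test(ds$counts, ds$groups, control = ds$control)
  }))

  markers <- stage_fail("population_markers", population_markers(
    study$niche$counts, study$niche$meta, min_cells = params$min_cells))
  calls <- stage_fail("call_enriched", call_enriched(
    markers, alpha = params$alpha, min_lfc = params$min_lfc,
    min_pct = params$min_pct, cap = params$lfc_cap))

  ledger <- stage_fail("cascade", build_receptor_ledger(
    de$bcCML, de$AML, study$screen$table, atlas, blacklist,
    study$lr$table, calls, alpha = params$alpha, fold = params$fold))
  edges <- stage_fail("build_interactome",
                      build_interactome(ledger, study$lr$table, calls))

  tensor <- stage_fail("stage_tensor", stage_tensor(
    study$niche$counts, study$niche$meta, stages = stages))
  classes <- stage_fail("classify_trajectory", classify_trajectories(
    tensor, theta_expr = params$theta_expr, theta_cv = params$theta_cv))
  props <- stage_fail("population_proportions",
                      population_proportions(study$niche$meta, stages = stages))

  panel <- if (params$prognosis_scope == "survivors") {
    ledger$gene[ledger$survivor]
  } else {
    ledger$gene[!ledger$blacklisted]
  }
  panel <- intersect(panel, unique(study$survival$table$gene))
  prognosis <- stage_fail("prioritize", prioritize_receptors(
    study$survival$table, genes = panel, alpha = params$alpha,
    adjust = params$prognosis_adjust))

  report <- structure(list(
    de = de, ledger = ledger, counts = ledger_counts(ledger),
    markers = markers, calls = calls, edges = edges,
    tensor = tensor, classes = classes, proportions = props,
    prognosis = prognosis,
    provenance = list(
      package = "nichemapper",
      version = as.character(utils::packageVersion("nichemapper")),
      seed = seed, params = params
    )
  ), class = "pipeline_report")

  if (!is.null(out)) write_report(report, out)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  ct <- x$counts
  cat("<pipeline_report>\n")
  cat(sprintf("  receptor candidates: %d (both %d / AML %d / bcCML %d)\n",
              ct$candidates, ct$both, ct$AML_only, ct$bcCML_only))
  cat(sprintf("  misannotated removed: %d -> post-blacklist %d\n",
              ct$misannotated, ct$post_blacklist))
  cat(sprintf("  ligand exclusions: %d no known ligand, %d no enriched ligand\n",
              ct$no_known_ligand, ct$no_enriched_ligand))
  cat(sprintf("  final receptors: %d; interactome edges: %d\n",
              ct$survivors, nrow(x$edges)))
  cat(sprintf("  temporal classes: %s\n",
              paste(names(table(x$classes$class)),
                    table(x$classes$class), sep = "=", collapse = ", ")))
  cat(sprintf("  poor-prognosis receptors: %s\n",
              paste(x$prognosis$gene[x$prognosis$poor_prognosis],
                    collapse = ", ")))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' `ledger.tsv`, `edges.tsv` and a lossless `report.json` (summary counts,
#' temporal class table, prognostic flags, provenance). Numeric TSV columns
#' use fixed 6-significant-digit formatting so reruns at the same seed are
#' byte-identical.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_stable(report$ledger, file.path(dir, "ledger.tsv"))
  write_tsv_stable(report$edges, file.path(dir, "edges.tsv"))
  class_tab <- as.list(table(report$classes$class))
  json <- list(
    counts = as.list(report$counts),
    edge_count = nrow(report$edges),
    temporal_classes = class_tab,
    poor_prognosis = report$prognosis$gene[report$prognosis$poor_prognosis],
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(dir)
}
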