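# The receptor-candidate filtering cascade. Each step is a small set
# operation; build_receptor_ledger() composes them into the auditable trail
# from differential expression down to the final interactome receptors.

#' Significantly upregulated genes
#'
#' Filters a differential-expression table for genes with `padj < alpha` and
#' `log2fc > min_lfc` (both boundaries strict).
#'
#' @param de Tibble from [de_test()] (`gene`, `log2fc`, `padj`).
#' @param alpha Adjusted-p threshold (strict).
#' @param min_lfc Fold-change threshold (strict), default 0.
#' @return Character vector of gene identifiers.
#' @export
select_upregulated <- function(de, alpha = 0.05, min_lfc = 0) {
  if (nrow(de) == 0) stop("empty differential-expression table", call. = FALSE)
  de$gene[de$padj < alpha & de$log2fc > min_lfc]
}

#' Screen dropout genes
#'
#' A gene drops out when the aggregate of its per-guide log2 fold-changes is
#' at or below `-log2(fold)` (inclusive: a two-fold depletion counts).
#'
#' @param screen Tibble `gene`, `guide`, `log2fc`.
#' @param fold Depletion fold threshold (> 1), default 2.
#' @param aggregate Guide aggregation: `median` (default), `mean`, or
#'   `second_best` (second most negative guide).
#' @return Character vector of dropout genes.
#' @export
screen_dropouts <- function(screen, fold = 2, aggregate = c("median", "mean", "second_best")) {
  if (fold <= 1) stop("`fold` must exceed 1", call. = FALSE)
  aggregate <- match.arg(aggregate)
  agg_fun <- switch(aggregate,
    median = stats::median,
    mean = mean,
    second_best = function(x) if (length(x) < 2) x[1] else sort(x)[2]
  )
  ok <- !is.na(screen$log2fc)
  if (any(!ok)) {
    dropped <- unique(screen$gene[!ok])
    warning("guides with missing log2fc skipped for: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    screen <- screen[ok, ]
  }
  agg <- screen |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(score = agg_fun(.data$log2fc), .groups = "drop")
  agg$gene[agg$score <= -log2(fold)]
}

#' Surface-atlas filter with misannotation blacklist
#'
#' Keeps genes annotated as cell surface in the atlas, then removes genes on
#' the misannotation blacklist (tagged `misannotated`).
#'
#' @param genes Candidate gene set.
#' @param atlas Surface-atlas gene set.
#' @param blacklist Misannotated genes to remove after the atlas intersection.
#' @return List with `kept` and `removed` character vectors.
#' @export
surface_filter <- function(genes, atlas, blacklist = character()) {
  on_surface <- intersect(genes, atlas)
  list(kept = setdiff(on_surface, blacklist),
       removed = intersect(genes, blacklist))
}

#' Disease-category map
#'
#' Splits candidate sets from two diseases into shared and disease-unique
#' categories.
#'
#' @param bc,aml Candidate gene sets for bcCML and AML.
#' @return Tibble `gene`, `category` in `both` / `bcCML_only` / `AML_only`.
#' @export
categorize <- function(bc, aml) {
  dplyr::bind_rows(
    tibble::tibble(gene = intersect(bc, aml), category = "both"),
    tibble::tibble(gene = setdiff(bc, aml), category = "bcCML_only"),
    tibble::tibble(gene = setdiff(aml, bc), category = "AML_only")
  )
}

#' Exclude receptors by ligand evidence
#'
#' A receptor with no interaction-table row is excluded as `no_known_ligand`;
#' a receptor none of whose ligands carries a passing enrichment call in any
#' microenvironment population is excluded as `no_enriched_ligand`.
#'
#' @param receptors Receptor gene set (post-blacklist candidates).
#' @param lr Interaction table (`ligand`, `receptor`).
#' @param calls Passing ligand calls from [call_enriched()] (`ligand`,
#'   `population`, ...).
#' @return Tibble `gene`, `exclusion_reason` (`none` for survivors).
#' @export
exclude_by_ligand <- function(receptors, lr, calls) {
  reason <- vapply(receptors, function(r) {
    ligands <- lr$ligand[lr$receptor == r]
    if (length(ligands) == 0) return("no_known_ligand")
    if (!any(ligands %in% calls$ligand)) return("no_enriched_ligand")
    "none"
  }, character(1))
  tibble::tibble(gene = receptors, exclusion_reason = unname(reason))
}

#' Build the full receptor-candidate ledger
#'
#' Composes the cascade: per-disease upregulated genes are intersected with
#' the surface atlas and the screen dropout set, categorized by disease
#' overlap, stripped of blacklisted (misannotated) genes, and finally filtered
#' by ligand evidence. Every input candidate appears exactly once with its
#' filter flags and exclusion reason, so
#' `n(candidates) = n(survivors) + sum(per-reason exclusions)` holds by
#' construction and is asserted.
#'
#' @param de_bc,de_aml Differential-expression tables (disease vs control).
#' @param screen Screen table (`gene`, `guide`, `log2fc`).
#' @param atlas,blacklist Surface annotation and misannotation blacklist.
#' @param lr Ligand-receptor interaction table.
#' @param calls Passing ligand calls ([call_enriched()]).
#' @param alpha,fold Thresholds for [select_upregulated()] and
#'   [screen_dropouts()].
#' @return A `receptor_ledger` tibble: `gene`, `category`, `upregulated_bc`,
#'   `upregulated_aml`, `surface`, `screen_dropout`, `blacklisted`,
#'   `exclusion_reason`, `survivor`.
#' @export
build_receptor_ledger <- function(de_bc, de_aml, screen, atlas, blacklist,
                                  lr, calls, alpha = 0.05, fold = 2) {
  up_bc <- select_upregulated(de_bc, alpha)
  up_aml <- select_upregulated(de_aml, alpha)
  dropouts <- screen_dropouts(screen, fold)

  cand_bc <- intersect(intersect(up_bc, atlas), dropouts)
  cand_aml <- intersect(intersect(up_aml, atlas), dropouts)
  cats <- categorize(cand_bc, cand_aml)

  sf <- surface_filter(cats$gene, atlas, blacklist)
  lig <- exclude_by_ligand(sf$kept, lr, calls)

  ledger <- cats |>
    dplyr::mutate(
      upregulated_bc = .data$gene %in% up_bc,
      upregulated_aml = .data$gene %in% up_aml,
      surface = TRUE,
      screen_dropout = TRUE,
      blacklisted = .data$gene %in% sf$removed
    ) |>
    dplyr::left_join(lig, by = "gene") |>
    dplyr::mutate(
      exclusion_reason = dplyr::if_else(.data$blacklisted, "misannotated",
                                        .data$exclusion_reason),
      survivor = .data$exclusion_reason == "none"
    ) |>
    dplyr::arrange(.data$gene)

  stopifnot(nrow(ledger) == sum(ledger$survivor) +
              sum(ledger$exclusion_reason != "none"))
  class(ledger) <- c("receptor_ledger", class(ledger))
  ledger
}

#' Summary counts of a receptor ledger
#'
#' @param ledger A `receptor_ledger` tibble.
#' @return One-row tibble: total candidates, per-category counts, blacklist
#'   removals, post-blacklist candidates, per-reason exclusions, survivors.
#' @export
ledger_counts <- function(ledger) {
  tibble::tibble(
    candidates = nrow(ledger),
    both = sum(ledger$category == "both"),
    AML_only = sum(ledger$category == "AML_only"),
    bcCML_only = sum(ledger$category == "bcCML_only"),
    misannotated = sum(ledger$exclusion_reason == "misannotated"),
    post_blacklist = nrow(ledger) - sum(ledger$exclusion_reason == "misannotated"),
    no_known_ligand = sum(ledger$exclusion_reason == "no_known_ligand"),
    no_enriched_ligand = sum(ledger$exclusion_reason == "no_enriched_ligand"),
    survivors = sum(ledger$survivor)
  )
}
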