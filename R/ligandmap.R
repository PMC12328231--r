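# Per-population ligand enrichment and interactome assembly.

#' Depth-normalize single-cell counts
#'
#' Scales each cell to 10,000 counts and applies `log1p` — the common
#' single-cell convention used ahead of marker testing.
#'
#' @param counts Genes x cells count matrix.
#' @param scale_factor Target per-cell depth before the log transform.
#' @return Matrix of log-normalized expression, same shape.
#' @export
normalize_cells <- function(counts, scale_factor = 1e4) {
  assert_count_matrix(counts)
  cs <- colSums(counts)
  cs[cs == 0] <- 1  # empty cells stay all-zero rather than dividing by zero
  log1p(t(t(counts) / cs) * scale_factor)
}

#' One-vs-rest population marker tests
#'
#' For each requested gene and each population, runs a rank-sum test of the
#' population's cells against all other cells on log-normalized expression,
#' with a pseudocount fold-change of group means and detection fractions
#' (fraction of cells with count > 0). Adjusted p-values are BH across all
#' (gene, population) rows of the returned table.
#'
#' @param counts Genes x cells count matrix.
#' @param meta Cell metadata tibble with `cell_id` and `population` columns
#'   matching the matrix columns.
#' @param genes Genes to test (default: all rows).
#' @param min_cells Populations with fewer cells are skipped with a warning.
#' @return Tibble `gene`, `population`, `statistic`, `p`, `padj`, `log2fc`,
#'   `pct_in`, `pct_out`.
#' @export
population_markers <- function(counts, meta, genes = NULL, min_cells = 10) {
  assert_count_matrix(counts)
  if (!all(colnames(counts) %in% meta$cell_id)) {
    stop("every cell column needs a metadata row", call. = FALSE)
  }
  pop <- meta$population[match(colnames(counts), meta$cell_id)]
  pops <- sort(unique(pop))
  if (length(pops) < 2) stop("need at least 2 populations", call. = FALSE)
  genes <- genes %||% rownames(counts)
  missing <- setdiff(genes, rownames(counts))
  if (length(missing) > 0) {
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  norm <- normalize_cells(counts[genes, , drop = FALSE])
  raw <- counts[genes, , drop = FALSE]

  rows <- list()
  for (p in pops) {
    in_p <- pop == p
    if (sum(in_p) < min_cells) {
      warning("population ", p, " has fewer than ", min_cells,
              " cells; skipped", call. = FALSE)
      next
    }
    for (g in genes) {
      x <- norm[g, in_p]
      y <- norm[g, !in_p]
      rs <- rank_sum(x, y)
      lfc <- log2((mean(expm1(x)) + 0.5) / (mean(expm1(y)) + 0.5))
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, population = p,
        statistic = rs$statistic, p = rs$p,
        log2fc = lfc,
        pct_in = mean(raw[g, in_p] > 0),
        pct_out = mean(raw[g, !in_p] > 0)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$padj <- bh_adjust(out$p)
  out[, c("gene", "population", "statistic", "p", "padj",
          "log2fc", "pct_in", "pct_out")]
}

#' Call enriched ligands
#'
#' A (ligand, population) marker row passes when `padj < alpha`,
#' `log2fc > min_lfc` and `pct_in >= min_pct`. Passing calls get a capped
#' effect size `log2fc_capped = min(log2fc, cap)` for export.
#'
#' @param markers Marker table from [population_markers()].
#' @param alpha Adjusted-p threshold.
#' @param min_lfc Fold-change threshold (strict).
#' @param min_pct Minimum detection fraction in the target population.
#' @param cap Export cap on the log2 fold-change.
#' @return Tibble of passing calls with `ligand`, `population`, `log2fc`,
#'   `log2fc_capped`, `p`, `padj`, `pct_in`, `pct_out`.
#' @export
call_enriched <- function(markers, alpha = 0.05, min_lfc = 0,
                          min_pct = 0.1, cap = 5) {
  markers |>
    dplyr::filter(.data$padj < alpha,
                  .data$log2fc > min_lfc,
                  .data$pct_in >= min_pct) |>
    dplyr::transmute(
      ligand = .data$gene,
      population = .data$population,
      log2fc = .data$log2fc,
      log2fc_capped = pmin(.data$log2fc, cap),
      p = .data$p, padj = .data$padj,
      pct_in = .data$pct_in, pct_out = .data$pct_out
    )
}

#' Assemble the receptor-ligand interactome
#'
#' One edge per (surviving receptor, enriched ligand) pair linked by the
#' interaction table; the edge carries the set of populations where the
#' ligand passes and the maximum capped fold-change as weight. Edges are
#' deterministically sorted by (receptor, ligand).
#'
#' @param ledger Receptor ledger from [build_receptor_ledger()].
#' @param lr Interaction table (`ligand`, `receptor`).
#' @param calls Passing ligand calls from [call_enriched()].
#' @return Tibble `receptor`, `ligand`, `populations` (";"-joined, sorted),
#'   `weight`.
#' @export
build_interactome <- function(ledger, lr, calls) {
  survivors <- ledger$gene[ledger$survivor]
  edges <- lr |>
    dplyr::filter(.data$receptor %in% survivors) |>
    dplyr::inner_join(calls, by = "ligand", relationship = "many-to-many") |>
    dplyr::group_by(.data$receptor, .data$ligand) |>
    dplyr::summarise(
      populations = paste(sort(unique(.data$population)), collapse = ";"),
      weight = max(.data$log2fc_capped),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$receptor, .data$ligand)
  stopifnot(all(edges$receptor %in% survivors))
  edges
}

#' Long-format circos export of an interactome
#'
#' @param edges Edge table from [build_interactome()].
#' @return Tibble `sector`, `partner`, `value`: one row per edge with the
#'   receptor as sector and the ligand as partner, weighted by the capped
#'   fold-change.
#' @export
circos_export <- function(edges) {
  tibble::tibble(sector = edges$receptor, partner = edges$ligand,
                 value = edges$weight)
}
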