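# Stage-resolved expression summaries, four-class ligand trajectory
# classification, trajectory clustering, and population-proportion dynamics.

TEMPORAL_CLASSES <- c("steady", "lost", "transient", "population_shift",
                      "unclassified")

#' Stage-resolved expression tensor
#'
#' Mean log-normalized expression and detection fraction per
#' (gene, population, stage), in long tidy form.
#'
#' @param counts Genes x cells count matrix.
#' @param meta Cell metadata with `cell_id`, `population`, `stage`.
#' @param stages The ordered stage labels; all four must be present in `meta`.
#' @param genes Genes to summarise (default all).
#' @return A `stage_tensor` tibble: `gene`, `population`, `stage`,
#'   `mean_expr`, `detection`, with `stage` an ordered factor.
#' @export
stage_tensor <- function(counts, meta,
                         stages = c("naive", "initiation", "expansion", "end"),
                         genes = NULL) {
  assert_count_matrix(counts)
  if (!all(colnames(counts) %in% meta$cell_id)) {
    stop("every cell column needs a metadata row", call. = FALSE)
  }
  idx <- match(colnames(counts), meta$cell_id)
  pop <- meta$population[idx]
  stg <- meta$stage[idx]
  absent <- setdiff(stages, unique(stg))
  if (length(absent) > 0) {
    stop("missing stage(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  genes <- genes %||% rownames(counts)
  norm <- normalize_cells(counts[genes, , drop = FALSE])
  raw <- counts[genes, , drop = FALSE]

  groups <- interaction(pop, stg, drop = FALSE, sep = "\r")
  mean_by <- t(apply(norm, 1, function(v) tapply(v, groups, mean)))
  det_by <- t(apply(raw, 1, function(v) tapply(v, groups, function(z) mean(z > 0))))
  keys <- strsplit(colnames(mean_by), "\r", fixed = TRUE)

  out <- tibble::tibble(
    gene = rep(genes, times = length(keys)),
    population = rep(vapply(keys, `[`, "", 1), each = length(genes)),
    stage = rep(vapply(keys, `[`, "", 2), each = length(genes)),
    mean_expr = as.vector(mean_by),
    detection = as.vector(det_by)
  ) |>
    dplyr::filter(!is.na(.data$mean_expr)) |>
    dplyr::mutate(stage = factor(.data$stage, levels = stages, ordered = TRUE)) |>
    dplyr::arrange(.data$gene, .data$population, .data$stage)
  class(out) <- c("stage_tensor", class(out))
  out
}

# Which populations count as "expressing" a gene at a stage.
expressed_matrix <- function(slice, theta_expr) {
  det <- tidyr::pivot_wider(slice[, c("population", "stage", "detection")],
                            names_from = "stage", values_from = "detection")
  m <- as.matrix(det[, -1])
  rownames(m) <- det$population
  m >= theta_expr
}

#' Classify one gene's temporal trajectory
#'
#' Assigns exactly one of the four temporal classes (or `unclassified`) from
#' the gene's detection pattern across the four ordered stages:
#' * `lost` — expressed at naive and/or initiation in some population, and in
#'   no population at the end stage;
#' * `transient` — not expressed at naive, expressed at an interior stage,
#'   not expressed at the end;
#' * `population_shift` — some population expressed at every stage, but the
#'   top-expressing population differs between stages (argmax ties broken
#'   lexicographically by population label). A stage's top population only
#'   counts as distinct when it dominates the runner-up by `theta_dom`-fold
#'   in mean expression, so ubiquitous genes with population-comparable
#'   levels are not called shifts on estimation noise;
#' * `steady` — one population expressed at all four stages with a trajectory
#'   coefficient of variation below `theta_cv`.
#' Precedence: lost > transient > population_shift > steady.
#'
#' @param tensor A [stage_tensor()].
#' @param gene Gene identifier.
#' @param theta_expr Detection fraction at or above which a (population,
#'   stage) counts as expressed.
#' @param theta_cv Coefficient-of-variation bound for `steady`.
#' @param theta_dom Fold-dominance the top population needs over the
#'   runner-up for a stage to contribute to `population_shift`.
#' @return A single class label.
#' @export
classify_trajectory <- function(tensor, gene, theta_expr = 0.1, theta_cv = 0.5,
                                theta_dom = 2) {
  slice <- tensor[tensor$gene == gene, ]
  if (nrow(slice) == 0) stop("gene not in tensor: ", gene, call. = FALSE)
  ex <- expressed_matrix(slice, theta_expr)
  n_stage <- ncol(ex)
  any_by_stage <- apply(ex, 2, any)

  # lost: on at naive (possibly persisting into later stages), off at end.
  # Requiring the naive stage keeps this disjoint from transient, whose
  # template switches on only after naive.
  if (any(ex[, 1]) && !any_by_stage[n_stage]) {
    return("lost")
  }
  # transient: off at naive, on inside, off at end
  if (!any_by_stage[1] && any(any_by_stage[2:(n_stage - 1)]) &&
      !any_by_stage[n_stage]) {
    return("transient")
  }
  # population_shift: covered at every stage, dominant population moves
  if (all(any_by_stage)) {
    mean_w <- tidyr::pivot_wider(slice[, c("population", "stage", "mean_expr")],
                                 names_from = "stage", values_from = "mean_expr")
    mm <- as.matrix(mean_w[, -1])
    rownames(mm) <- mean_w$population
    ord <- order(rownames(mm))  # lexicographic tie-break
    mm <- mm[ord, , drop = FALSE]
    argmax <- rownames(mm)[apply(mm, 2, which.max)]
    dominant <- apply(mm, 2, function(v) {
      s <- sort(v, decreasing = TRUE)
      length(s) < 2 || s[1] >= theta_dom * s[2]
    })
    if (any(dominant) && length(unique(argmax[dominant])) > 1) {
      return("population_shift")
    }
  }
  # steady: one population on at all stages, flat trajectory
  always_on <- rownames(ex)[apply(ex, 1, all)]
  if (length(always_on) > 0) {
    for (p in always_on) {
      traj <- slice$mean_expr[slice$population == p][order(slice$stage[slice$population == p])]
      cv <- stats::sd(traj) / mean(traj)
      if (is.finite(cv) && cv < theta_cv) return("steady")
    }
  }
  "unclassified"
}

#' Classify several genes
#'
#' @param tensor A [stage_tensor()].
#' @param genes Genes to classify (default: all in the tensor).
#' @inheritParams classify_trajectory
#' @return Tibble `gene`, `class`.
#' @export
classify_trajectories <- function(tensor, genes = NULL, theta_expr = 0.1,
                                  theta_cv = 0.5, theta_dom = 2) {
  genes <- genes %||% unique(tensor$gene)
  tibble::tibble(
    gene = genes,
    class = vapply(genes, classify_trajectory, character(1),
                   tensor = tensor, theta_expr = theta_expr,
                   theta_cv = theta_cv, theta_dom = theta_dom)
  )
}

#' Cluster stage trajectories within a population
#'
#' Per-gene trajectories (mean expression across the four stages in one
#' population) are z-scored, compared by correlation distance
#' (`1 - Pearson r`), and grouped by average-linkage hierarchical clustering
#' cut at `k` clusters or height `h`. Zero-variance genes go to a dedicated
#' `flat` cluster (cluster 0) and are excluded from the correlation
#' clustering. Each cluster gets a consensus (mean z) trajectory and a
#' monotone-direction tag.
#'
#' @param tensor A [stage_tensor()].
#' @param population Population whose trajectories to cluster.
#' @param k Number of clusters (exclusive with `h`).
#' @param h Cut height on the dendrogram (correlation-distance scale).
#' @return List with `clusters` (tibble `gene`, `cluster`) and `consensus`
#'   (tibble `cluster`, `stage`, `z`, `trend`).
#' @export
cluster_trajectories <- function(tensor, population, k = NULL, h = NULL) {
  if (is.null(k) == is.null(h)) {
    stop("supply exactly one of `k` or `h`", call. = FALSE)
  }
  slice <- tensor[tensor$population == population, ]
  wide <- tidyr::pivot_wider(slice[, c("gene", "stage", "mean_expr")],
                             names_from = "stage", values_from = "mean_expr")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene
  v <- apply(m, 1, stats::var)
  flat <- rownames(m)[v == 0]
  live <- m[v > 0, , drop = FALSE]
  if (nrow(live) < 2) stop("need at least 2 genes with nonzero variance",
                           call. = FALSE)
  z <- t(scale(t(live)))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  cl <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)

  clusters <- dplyr::bind_rows(
    tibble::tibble(gene = names(cl), cluster = unname(cl)),
    tibble::tibble(gene = flat, cluster = 0L)
  )
  consensus <- tibble::tibble(
    gene = rep(names(cl), times = ncol(z)),
    cluster = rep(unname(cl), times = ncol(z)),
    stage = rep(colnames(z), each = nrow(z)),
    z = as.vector(z)
  ) |>
    dplyr::group_by(.data$cluster, .data$stage) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop") |>
    dplyr::mutate(stage = factor(.data$stage, levels = colnames(z),
                                 ordered = TRUE)) |>
    dplyr::arrange(.data$cluster, .data$stage)
  trend <- consensus |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(trend = monotone_tag(.data$z), .groups = "drop")
  consensus <- dplyr::left_join(consensus, trend, by = "cluster")
  list(clusters = clusters, consensus = consensus)
}

monotone_tag <- function(z) {
  d <- diff(z)
  if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else "other"
}

#' Population proportions over stages with trend tags
#'
#' Fraction of cells per population at each stage, with a monotone-trend tag
#' from the Spearman correlation between stage index and proportion
#' (`|rho| >= 0.8` required to tag; over four stages only a perfectly
#' monotone drift qualifies).
#'
#' @param meta Cell metadata with `population` and `stage`.
#' @param stages Ordered stage labels; all must be present.
#' @return Tibble `population`, `stage`, `n`, `proportion`, `rho`, `trend`.
#' @export
population_proportions <- function(meta,
                                   stages = c("naive", "initiation",
                                              "expansion", "end")) {
  absent <- setdiff(stages, unique(meta$stage))
  if (length(absent) > 0) {
    stop("missing stage(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  props <- meta |>
    dplyr::count(.data$population, .data$stage) |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(population = unique(meta$population),
                    stage = stages, fill = list(n = 0L, proportion = 0)) |>
    dplyr::mutate(stage = factor(.data$stage, levels = stages,
                                 ordered = TRUE)) |>
    dplyr::arrange(.data$population, .data$stage)
  trends <- props |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      rho = if (stats::sd(.data$proportion) == 0) 0 else
        suppressWarnings(stats::cor(as.integer(.data$stage), .data$proportion,
                                    method = "spearman")),
      .groups = "drop"
    ) |>
    dplyr::mutate(trend = dplyr::case_when(
      .data$rho >= 0.8 ~ "increasing",
      .data$rho <= -0.8 ~ "decreasing",
      TRUE ~ "none"
    ))
  dplyr::left_join(props, trends, by = "population")
}
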