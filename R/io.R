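# Readers and writers for the documented plain-text schemas: counts as TSV
# or MatrixMarket with gene/cell sidecars, and the simulated study bundle.

#' Read a count matrix
#'
#' TSV format: first column gene identifiers, header row sample identifiers,
#' integer counts. MatrixMarket format: coordinate `.mtx` with `genes.tsv`
#' and `cells.tsv` sidecars in the same directory.
#'
#' @param path File path (`.tsv` table or `.mtx` matrix).
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @return Integer matrix, genes in rows.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") read_counts_tsv(path) else read_counts_mtx(path)
}

read_counts_tsv <- function(path) {
  if (file.size(path) == 0) stop("empty counts file: ", path, call. = FALSE)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop("ragged row at line ", bad, " of ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts table needs a gene column plus samples",
                         call. = FALSE)
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop("duplicate gene identifiers: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_col <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))][1]
    stop("non-numeric counts in column ", bad_col, call. = FALSE)
  }
  if (any(m != floor(m)) || any(m < 0)) {
    bad <- which(m != floor(m) | m < 0, arr.ind = TRUE)[1, ]
    stop("non-integer or negative count at gene ", genes[bad[1]],
         ", sample ", colnames(m)[bad[2]], call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

read_counts_mtx <- function(path) {
  m <- tryCatch(Matrix::readMM(path), error = function(e) {
    stop("invalid MatrixMarket file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  dir <- dirname(path)
  gene_f <- file.path(dir, "genes.tsv")
  cell_f <- file.path(dir, "cells.tsv")
  for (f in c(gene_f, cell_f)) {
    if (!file.exists(f)) stop("missing sidecar: ", f, call. = FALSE)
  }
  genes <- readLines(gene_f)
  cells <- readLines(cell_f)
  if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
    stop("sidecar lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in genes.tsv",
                                 call. = FALSE)
  out <- as.matrix(m)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(genes, cells)
  out
}

#' Write a count matrix
#'
#' @param counts Gene-by-sample integer matrix.
#' @param path Output path; `.mtx` writes MatrixMarket plus `genes.tsv` /
#'   `cells.tsv` sidecars, anything else writes TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  assert_count_matrix(counts)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(counts), file.path(dirname(path), "cells.tsv"))
  } else {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Numeric columns at fixed 6 significant digits for byte-stable diffs.
write_tsv_stable <- function(df, path) {
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SIM_FILES <- c("bulk_bcCML_counts.tsv", "bulk_bcCML_samples.tsv",
               "bulk_AML_counts.tsv", "bulk_AML_samples.tsv",
               "screen.tsv", "niche_counts.mtx", "genes.tsv", "cells.tsv",
               "cell_metadata.tsv", "lr_pairs.tsv", "survival.tsv",
               "dose_single.tsv", "dose_combo.tsv", "truth.json", "study.json")

#' Write a simulated study to a directory
#'
#' Emits the documented plain-text bundle: bulk counts and sample sheets per
#' disease (TSV), the screen table, single-cell counts as MatrixMarket with
#' sidecars plus cell metadata, the interaction, survival and dose-response
#' tables, the ground-truth ledger (`truth.json`) and a small `study.json`
#' with the seed and stage order.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  stopifnot(inherits(study, "nm_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (disease in names(study$bulk$datasets)) {
    ds <- study$bulk$datasets[[disease]]
    write_counts(ds$counts, file.path(dir, sprintf("bulk_%s_counts.tsv", disease)))
    write_tsv_stable(
      data.frame(sample = colnames(ds$counts), group = ds$groups),
      file.path(dir, sprintf("bulk_%s_samples.tsv", disease))
    )
  }
  write_tsv_stable(study$screen$table, file.path(dir, "screen.tsv"))
  write_counts(study$niche$counts, file.path(dir, "niche_counts.mtx"))
  write_tsv_stable(study$niche$meta, file.path(dir, "cell_metadata.tsv"))
  write_tsv_stable(study$lr$table, file.path(dir, "lr_pairs.tsv"))
  write_tsv_stable(study$survival$table, file.path(dir, "survival.tsv"))
  write_tsv_stable(study$dose$single, file.path(dir, "dose_single.tsv"))
  write_tsv_stable(study$dose$combo, file.path(dir, "dose_combo.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(seed = study$config$seed,
                            stages = study$config$stages,
                            atlas = study$config$atlas_genes,
                            blacklist = study$config$blacklist_genes),
                       file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulated study bundle
#'
#' Validates that every expected file exists (failing before any computation
#' with the offending path) and reassembles the study object consumed by
#' [run_all()].
#'
#' @param dir Directory written by [write_simulation()].
#' @return An `nm_study`-shaped list (without the generating config).
#' @export
read_simulation <- function(dir) {
  missing <- SIM_FILES[!file.exists(file.path(dir, SIM_FILES))]
  if (length(missing) > 0) {
    stop("missing input file(s): ",
         paste(file.path(dir, missing), collapse = ", "), call. = FALSE)
  }
  meta_json <- jsonlite::read_json(file.path(dir, "study.json"),
                                   simplifyVector = TRUE)
  datasets <- list()
  for (disease in c("bcCML", "AML")) {
    counts <- read_counts(file.path(dir, sprintf("bulk_%s_counts.tsv", disease)))
    samples <- utils::read.delim(file.path(dir, sprintf("bulk_%s_samples.tsv", disease)))
    datasets[[disease]] <- list(counts = counts,
                                groups = samples$group[match(colnames(counts),
                                                             samples$sample)],
                                control = "control")
  }
  structure(list(
    bulk = list(datasets = datasets),
    screen = list(table = tibble::as_tibble(
      utils::read.delim(file.path(dir, "screen.tsv")))),
    niche = list(counts = read_counts(file.path(dir, "niche_counts.mtx")),
                 meta = tibble::as_tibble(
                   utils::read.delim(file.path(dir, "cell_metadata.tsv")))),
    survival = list(table = tibble::as_tibble(
      utils::read.delim(file.path(dir, "survival.tsv")))),
    lr = list(table = tibble::as_tibble(
      utils::read.delim(file.path(dir, "lr_pairs.tsv")))),
    dose = list(single = tibble::as_tibble(
      utils::read.delim(file.path(dir, "dose_single.tsv"))),
      combo = tibble::as_tibble(
        utils::read.delim(file.path(dir, "dose_combo.tsv")))),
    meta = meta_json
  ), class = "nm_study")
}
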