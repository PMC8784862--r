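#' Assemble a validated single-cell data container
#'
#' Bundles a genes x cells count matrix with its cell-level and
#' individual-level metadata, validates the cross-references, and attaches
#' the per-cell log read depth (`log_rd`) as the default cell-level
#' covariate. Cells with zero total count are dropped (their log read depth
#' is undefined) with a warning.
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (base matrix or a `Matrix` sparse matrix). Row names are gene ids and
#'   column names are cell ids unless `gene_ids`/`cell_ids` are given.
#' @param cell_meta data frame keyed by cell id (column `cell`), with a
#'   mandatory `individual` column and zero or more numeric cell-level
#'   covariates.
#' @param indiv_meta data frame keyed by individual id (column
#'   `individual`), holding the variable of interest and any
#'   individual-level covariates.
#' @param gene_ids,cell_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return An object of class `cell_data`: a list with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`, `indiv_meta`. `cell_meta` gains a
#'   `log_rd` column (natural log of the cell's total count) unless one is
#'   already present.
#' @export
cell_data <- function(counts, cell_meta, indiv_meta,
                      gene_ids = rownames(counts), cell_ids = colnames(counts)) {
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("counts must carry gene and cell ids (dimnames or explicit arguments)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop("gene/cell id lengths do not match the count matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicated cell ids")

  counts <- check_integer_counts(counts)
  dimnames(counts) <- list(gene_ids, cell_ids)

  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  indiv_meta <- as.data.frame(indiv_meta, stringsAsFactors = FALSE)
  if (!"cell" %in% names(cell_meta)) stop("cell_meta must have a 'cell' column")
  if (!"individual" %in% names(cell_meta))
    stop("cell_meta must have an 'individual' column")
  if (!"individual" %in% names(indiv_meta))
    stop("indiv_meta must have an 'individual' column")
  cell_meta$cell <- as.character(cell_meta$cell)
  cell_meta$individual <- as.character(cell_meta$individual)
  indiv_meta$individual <- as.character(indiv_meta$individual)
  if (anyDuplicated(cell_meta$cell)) stop("duplicated cell ids in cell_meta")
  if (anyDuplicated(indiv_meta$individual))
    stop("duplicated individual ids in indiv_meta")

  missing_cells <- setdiff(cell_ids, cell_meta$cell)
  if (length(missing_cells))
    stop("cells present in counts but absent from cell_meta: ",
         paste(utils::head(missing_cells, 5L), collapse = ", "))
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell), , drop = FALSE]
  rownames(cell_meta) <- NULL

  missing_ind <- setdiff(unique(cell_meta$individual), indiv_meta$individual)
  if (length(missing_ind))
    stop("individuals present in cell_meta but absent from indiv_meta: ",
         paste(missing_ind, collapse = ", "))

  rd <- read_depth(counts)
  zero_cells <- cell_ids[rd == 0]
  if (length(zero_cells)) {
    warning(length(zero_cells), " cell(s) with zero total count excluded: ",
            paste(utils::head(zero_cells, 5L), collapse = ", "))
    keep <- rd > 0
    counts <- counts[, keep, drop = FALSE]
    cell_ids <- cell_ids[keep]
    cell_meta <- cell_meta[keep, , drop = FALSE]
    rd <- rd[keep]
  }
  if (!"log_rd" %in% names(cell_meta)) cell_meta$log_rd <- log(rd)

  # restrict indiv_meta to individuals actually observed, keeping input order
  indiv_meta <- indiv_meta[indiv_meta$individual %in% cell_meta$individual, ,
                           drop = FALSE]
  rownames(indiv_meta) <- NULL
  if (nrow(indiv_meta) == 0L) stop("no individual has any retained cell")

  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta, indiv_meta = indiv_meta),
            class = "cell_data")
}

# Integer check with a small tolerance for MTX "real" dialects that store
# integers as floats; anything further from an integer is an error.
check_integer_counts <- function(counts, tol = 1e-8) {
  if (inherits(counts, "sparseMatrix")) {
    x <- counts@x
    if (any(x < 0)) stop("negative count entries")
    if (any(abs(x - round(x)) > tol)) stop("non-integer count entries")
    counts@x <- round(x)
  } else {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("negative count entries")
    if (any(abs(counts - round(counts)) > tol)) stop("non-integer count entries")
    counts <- round(counts)
  }
  counts
}

#' Per-cell read depth
#'
#' @param x a `cell_data` object or a genes x cells count matrix.
#' @return Named numeric vector of per-cell total counts (column sums).
#' @export
read_depth <- function(x) {
  m <- if (inherits(x, "cell_data")) x$counts else x
  if (inherits(m, "sparseMatrix")) Matrix::colSums(m) else colSums(m)
}

#' @export
print.cell_data <- function(x, ...) {
  cat("cell_data: ", nrow(x$counts), " genes x ", ncol(x$counts), " cells, ",
      nrow(x$indiv_meta), " individuals\n", sep = "")
  cat("cell covariates: ",
      paste(setdiff(names(x$cell_meta), c("cell", "individual")), collapse = ", "),
      "\n", sep = "")
  cat("individual columns: ",
      paste(setdiff(names(x$indiv_meta), "individual"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Load single-cell count data and metadata from disk
#'
#' Reads either a MatrixMarket sparse matrix with gene/cell id sidecar files
#' or a single dense delimited table (header row = cell ids, first column =
#' gene ids), plus cell- and individual-level metadata tables, and returns a
#' validated [cell_data()] container.
#'
#' @param counts_path path to the count matrix: either a `.mtx` file (with
#'   sidecars, see `genes_path`/`cells_path`) or a TSV/CSV dense table.
#' @param cell_meta_path,indiv_meta_path paths to TSV/CSV metadata tables
#'   with a header row; `cell_meta` needs columns `cell` and `individual`,
#'   `indiv_meta` needs `individual`.
#' @param genes_path,cells_path sidecar files with one gene (cell) id per
#'   line; default `genes.tsv` / `barcodes.tsv` next to the `.mtx` file.
#'   Ignored for dense input.
#' @param transpose set `TRUE` when the matrix on disk is cells x genes.
#' @return A [cell_data()] object.
#' @export
load_cell_data <- function(counts_path, cell_meta_path, indiv_meta_path,
                           genes_path = NULL, cells_path = NULL,
                           transpose = FALSE) {
  if (grepl("\\.mtx(\\.gz)?$", counts_path)) {
    dir <- dirname(counts_path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(cells_path)) cells_path <- file.path(dir, "barcodes.tsv")
    m <- Matrix::readMM(counts_path)
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    # sidecars may carry extra tab-separated columns (id<TAB>symbol); keep col 1
    genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[`, "", 1L)
    cells <- vapply(strsplit(cells, "\t", fixed = TRUE), `[`, "", 1L)
    if (transpose) m <- Matrix::t(m)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("matrix dimensions (", nrow(m), " x ", ncol(m),
           ") do not match id files (", length(genes), " genes, ",
           length(cells), " cells)")
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- utils::read.table(counts_path, header = TRUE, sep = guess_sep(counts_path),
                             row.names = 1L, check.names = FALSE)
    m <- as.matrix(tab)
    if (transpose) m <- t(m)
  }
  cm <- read_table_auto(cell_meta_path)
  im <- read_table_auto(indiv_meta_path)
  cell_data(m, cm, im)
}

guess_sep <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

read_table_auto <- function(path) {
  utils::read.table(path, header = TRUE, sep = guess_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Filter genes by expressed-cell fraction
#'
#' Keeps genes with a nonzero count in at least `min_frac` of all cells
#' (inclusive threshold). The cell set and all metadata are untouched.
#'
#' @param data a [cell_data()] object.
#' @param min_frac minimum fraction of cells with nonzero expression,
#'   in (0, 1]; default 0.20.
#' @return The filtered `cell_data`.
#' @export
filter_genes <- function(data, min_frac = 0.20) {
  stopifnot(inherits(data, "cell_data"), min_frac > 0, min_frac <= 1)
  m <- data$counts
  nz <- if (inherits(m, "sparseMatrix")) Matrix::rowSums(m > 0) else rowSums(m > 0)
  keep <- (nz / ncol(m)) >= min_frac
  if (!any(keep)) warning("no gene passes the expressed-fraction filter")
  data$counts <- m[keep, , drop = FALSE]
  data$gene_ids <- data$gene_ids[keep]
  data
}

#' Write per-gene test results to a TSV file
#'
#' @param results a data frame of per-gene results (as held in a `distde`
#'   object's `$results`) with columns `gene_id`, `F_stat`, `pvalue`,
#'   `n_perm_used`, `status` and optionally `qvalue`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_results <- function(results, path) {
  stopifnot(nrow(results) > 0)
  cols <- c("gene_id", "F_stat", "pvalue", "n_perm_used", "status")
  if ("qvalue" %in% names(results)) cols <- c(cols, "qvalue")
  out <- results[, cols, drop = FALSE]
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         sprintf("%.15g", out[[j]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path file path.
#' @return Data frame with the same columns.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}
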