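#' Sparse count table with per-cell annotations
#'
#' The universal input container: a genes x cells sparse matrix of
#' non-negative integer UMI counts together with per-cell metadata
#' (sample, age, sex, genotype, cell type, region) and the age ladder the
#' ages live on.
#'
#' @param counts genes x cells matrix (coerced to `dgCMatrix`); entries must
#'   be non-negative integers.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param cell_meta data.frame with one row per cell; required columns
#'   `cell_id`, `sample_id`, `age`, `sex`, `genotype`; optional `cell_type`
#'   and `region` (filled with `"unassigned"` when absent).
#' @param ladder an [age_ladder()]; every `age` value must be a member.
#' @return an object of class `cell_table`.
#' @export
cell_table <- function(counts, gene_ids, cell_meta, ladder) {
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(gene_ids))
    stop("format error: counts rows (", nrow(counts),
         ") != gene ids (", length(gene_ids), ")")
  if (anyDuplicated(gene_ids))
    stop("format error: duplicated gene_ids: ",
         paste(utils::head(gene_ids[duplicated(gene_ids)], 3L), collapse = ", "))
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  req <- c("cell_id", "sample_id", "age", "sex", "genotype")
  miss <- setdiff(req, names(cell_meta))
  if (length(miss))
    stop("format error: cell metadata missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(cell_meta) != ncol(counts))
    stop("format error: counts columns (", ncol(counts),
         ") != cell metadata rows (", nrow(cell_meta), ")")
  for (opt in c("cell_type", "region")) {
    if (is.null(cell_meta[[opt]])) cell_meta[[opt]] <- "unassigned"
  }
  cell_meta[] <- lapply(cell_meta, as.character)
  if (!inherits(ladder, "age_ladder")) stop("ladder must be an age_ladder")
  age_index(ladder, cell_meta$age)  # validation error on unknown labels
  bad_sex <- setdiff(unique(cell_meta$sex), c("F", "M"))
  if (length(bad_sex))
    stop("sex must be 'F' or 'M'; found: ", paste(bad_sex, collapse = ", "))
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(gene_ids, cell_meta$cell_id)
  rownames(cell_meta) <- NULL
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_meta = cell_meta,
         ladder = ladder),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d genes x %d cells, %d sample(s), ages %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              paste(intersect(x$ladder$labels, unique(x$cell_meta$age)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of cells / genes in a cell table
#' @param table a [cell_table()].
#' @return integer count.
#' @export
n_cells <- function(table) ncol(table$counts)

#' @rdname n_cells
#' @export
n_genes <- function(table) nrow(table$counts)

#' Subset a cell table by cells (and optionally genes)
#'
#' @param table a [cell_table()].
#' @param cells logical/integer/character index over cells.
#' @param genes optional index over genes.
#' @return a [cell_table()] restricted to the selection.
#' @export
subset_cells <- function(table, cells, genes = NULL) {
  if (is.character(cells)) cells <- match(cells, table$cell_meta$cell_id)
  meta <- table$cell_meta[cells, , drop = FALSE]
  counts <- table$counts[, cells, drop = FALSE]
  gid <- table$gene_ids
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, gid)
    counts <- counts[genes, , drop = FALSE]
    gid <- gid[genes]
  }
  cell_table(counts, gid, meta, table$ladder)
}

#' Read a cell table from Matrix Market + TSV files
#'
#' Expects the conventional on-disk trio: a coordinate-format `.mtx` count
#' matrix (genes x cells), a gene TSV whose first column is the gene id, and
#' a cell TSV with header columns `cell_id`, `sample_id`, `age`, `sex`,
#' `genotype` and optionally `cell_type`, `region`.
#'
#' @param matrix_path path to the MatrixMarket counts file.
#' @param gene_path path to the gene TSV (header `gene_id[, symbol]`).
#' @param cell_path path to the cell TSV (header as above).
#' @param ladder an [age_ladder()].
#' @return a validated [cell_table()].
#' @export
read_cell_table <- function(matrix_path, gene_path, cell_path, ladder) {
  counts <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(gene_path, header = TRUE,
                             colClasses = "character")
  cells <- utils::read.delim(cell_path, header = TRUE,
                             colClasses = "character")
  if (nrow(genes) != nrow(counts))
    stop("format error: gene table rows (", nrow(genes),
         ") != matrix rows (", nrow(counts), ")")
  if (nrow(cells) != ncol(counts))
    stop("format error: cell table rows (", nrow(cells),
         ") != matrix columns (", ncol(counts), ")")
  cell_table(counts, genes[[1L]], cells, ladder)
}

#' Write a cell table to Matrix Market + TSV files
#'
#' Inverse of [read_cell_table()]: writes `matrix.mtx`, `genes.tsv` and
#' `cells.tsv` under `dir`.
#'
#' @param table a [cell_table()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cell_table <- function(table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  m <- table$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, paths[1L])
  utils::write.table(data.frame(gene_id = table$gene_ids),
                     paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$cell_meta, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Per-cell library sizes (total UMIs)
#' @param table a [cell_table()].
#' @return numeric vector, one entry per cell.
#' @export
library_sizes <- function(table) {
  unname(Matrix::colSums(table$counts))
}
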