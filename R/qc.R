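#' Quality-control parameters for nucleus filtering
#'
#' Thresholds follow standard single-nucleus practice: nuclei are removed
#' when their total UMI count falls under `min_umi` or over `max_umi`, when
#' fewer than `min_genes` genes are detected, when more than
#' `max_top_gene_frac` of UMIs come from a single gene, when mitochondrial
#' or ribosomal UMI fractions exceed `max_mito_frac`/`max_ribo_frac`, or
#' when any other flagged list (immediate-early, apoptotic, red-blood-cell
#' genes) exceeds `max_flag_frac`.
#'
#' Flag gene lists are user-supplied gene-id vectors, named; the names
#' `mito` and `ribo` get their dedicated thresholds, every other list uses
#' `max_flag_frac`. Ids absent from the table are ignored with a warning.
#'
#' @param min_umi,max_umi inclusive bounds on the per-cell UMI total.
#' @param min_genes minimum number of detected genes.
#' @param max_top_gene_frac maximum fraction of UMIs from any one gene.
#' @param max_mito_frac,max_ribo_frac maximum mitochondrial / ribosomal UMI
#'   fractions.
#' @param max_flag_frac maximum UMI fraction for every other flagged list.
#' @param flag_gene_lists named list of character gene-id vectors.
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(min_umi = 400, max_umi = 100000, min_genes = 250,
                      max_top_gene_frac = 0.2, max_mito_frac = 0.1,
                      max_ribo_frac = 0.1, max_flag_frac = 0.01,
                      flag_gene_lists = list()) {
  stopifnot(min_umi > 0, min_umi < max_umi, min_genes >= 0)
  fr <- c(max_top_gene_frac, max_mito_frac, max_ribo_frac, max_flag_frac)
  if (any(fr <= 0) || any(fr > 1)) stop("fractions must lie in (0, 1]")
  if (length(flag_gene_lists) && is.null(names(flag_gene_lists)))
    stop("flag_gene_lists must be named")
  structure(
    list(min_umi = min_umi, max_umi = max_umi, min_genes = min_genes,
         max_top_gene_frac = max_top_gene_frac,
         max_mito_frac = max_mito_frac, max_ribo_frac = max_ribo_frac,
         max_flag_frac = max_flag_frac, flag_gene_lists = flag_gene_lists),
    class = "qc_params"
  )
}

#' Filter low-quality nuclei
#'
#' Applies every rule of [qc_params()] and keeps exactly the cells passing
#' all of them; genes are unchanged. Per-rule removal counts are reported as
#' messages and attached as attribute `qc_removed`.
#'
#' @param table a [cell_table()].
#' @param params a [qc_params()].
#' @param verbose report per-rule removal counts (default TRUE).
#' @return the filtered [cell_table()] (with attribute `qc_removed`).
#' @export
qc_filter <- function(table, params = qc_params(), verbose = TRUE) {
  stopifnot(inherits(params, "qc_params"))
  counts <- table$counts
  tot <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  topgene <- apply_max_per_col(counts)
  safe_tot <- pmax(tot, 1)  # zero-library cells fail min_umi regardless

  fails <- list(
    umi = tot < params$min_umi | tot > params$max_umi,
    genes = ngene < params$min_genes,
    top_gene = topgene / safe_tot > params$max_top_gene_frac
  )
  for (nm in names(params$flag_gene_lists)) {
    ids <- params$flag_gene_lists[[nm]]
    missing <- setdiff(ids, table$gene_ids)
    if (length(missing)) {
      warning(sprintf("qc list '%s': %d gene id(s) not in table, ignored",
                      nm, length(missing)))
      ids <- setdiff(ids, missing)
    }
    if (!length(ids)) next
    frac <- Matrix::colSums(counts[match(ids, table$gene_ids), ,
                                   drop = FALSE]) / safe_tot
    thr <- switch(nm, mito = params$max_mito_frac,
                  ribo = params$max_ribo_frac, params$max_flag_frac)
    fails[[nm]] <- frac > thr
  }
  removed <- vapply(fails, sum, 0)
  keep <- !Reduce(`|`, fails)
  if (verbose) {
    for (nm in names(removed))
      message(sprintf("qc_filter: rule '%s' removed %d cell(s)",
                      nm, removed[[nm]]))
    message(sprintf("qc_filter: kept %d of %d cells", sum(keep),
                    length(keep)))
  }
  if (!any(keep)) warning("qc_filter: no cells pass QC")
  out <- subset_cells(table, which(keep))
  attr(out, "qc_removed") <- removed
  out
}

# column-wise maximum of a sparse column matrix, zeros allowed
apply_max_per_col <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  p <- m@p
  x <- m@x
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    if (p[j + 1L] > p[j]) out[j] <- max(x[(p[j] + 1L):p[j + 1L]])
  }
  out
}
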