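#' Library-size log-normalization (log-CPX)
#'
#' Each count is divided by its cell's library size, multiplied by
#' `scale_factor` and passed through `log1p`. Cells with zero library size
#' map to all-zero columns. This is the standard log-normalization used as a
#' fully specifiable stand-in for variance-stabilizing transforms: the
#' downstream statistics only need a variance-stabilized embedding.
#'
#' @param table a [cell_table()] or a genes x cells (sparse) count matrix.
#' @param scale_factor positive scale, default `1e4`.
#' @return a genes x cells `dgCMatrix` of log-normalized values; the zero
#'   pattern of the counts is preserved.
#' @export
lognormalize <- function(table, scale_factor = 1e4) {
  m <- if (inherits(table, "cell_table")) table$counts else table
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  libs <- Matrix::colSums(m)
  libs[libs == 0] <- Inf  # all-zero cell stays all-zero
  # operate on the sparse slots directly: log1p(0) = 0 keeps sparsity
  j <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x / libs[j] * scale_factor)
  m
}

#' Per-gene centering, unit-variance scaling and clipping
#'
#' Centers each gene (row) and divides by its sample standard deviation
#' (n - 1 denominator), then clips to `[-clip, clip]`. Zero-variance genes
#' map to all-zero rows.
#'
#' @param matrix real genes x cells matrix (dense or sparse).
#' @param clip positive clipping bound, default 10.
#' @param center,scale optional precomputed per-gene centers / sds (used to
#'   apply a reference scaling to new cells).
#' @return a dense genes x cells matrix of scaled values; attributes
#'   `center` and `scale` hold the statistics used.
#' @export
scale_genes <- function(matrix, clip = 10, center = NULL, scale = NULL) {
  x <- as.matrix(matrix)
  if (is.null(center)) center <- rowMeans(x)
  if (is.null(scale)) {
    n <- ncol(x)
    scale <- if (n > 1) sqrt(rowSums((x - center)^2) / (n - 1)) else
      rep(0, nrow(x))
  }
  safe <- ifelse(scale > 0, scale, 1)
  out <- (x - center) / safe
  out[scale == 0, ] <- 0
  out[out > clip] <- clip
  out[out < -clip] <- -clip
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalized values and returns
#' the indices of the top `n` (all genes when fewer are available). Ties are
#' broken by gene order for determinism.
#'
#' @param norm_matrix genes x cells matrix of log-normalized values.
#' @param n number of genes to keep, default 2000.
#' @return integer vector of row indices, sorted ascending.
#' @export
select_hvg <- function(norm_matrix, n = 2000) {
  nc <- ncol(norm_matrix)
  if (nc < 2) return(seq_len(nrow(norm_matrix)))
  mu <- Matrix::rowMeans(norm_matrix)
  v <- (Matrix::rowSums(norm_matrix^2) - nc * mu^2) / (nc - 1)
  n <- min(n, length(v))
  sort(order(-v, seq_along(v))[seq_len(n)])
}

#' Principal component analysis of a genes x cells matrix
#'
#' Cells are observations. The matrix is gene-centered and decomposed by
#' SVD; scores are the projections of cells onto the top right-singular
#' directions. Variance fractions are singular values squared over the total
#' variance of the centered matrix. The sign of each component is fixed so
#' that its largest-magnitude gene loading is positive.
#'
#' @param matrix real genes x cells matrix.
#' @param n_components number of components to return.
#' @param cell_ids optional cell identifiers for the embedding index.
#' @return an object of class `embedding`: list with `scores`
#'   (cells x components), `variance_fractions`, `cell_index`, `rotation`
#'   (genes x components loadings) and `center` (per-gene means).
#' @export
pca <- function(matrix, n_components, cell_ids = NULL) {
  x <- t(as.matrix(matrix))  # cells x genes
  if (n_components < 1 || n_components > min(dim(x)))
    stop("validation error: n_components must be in [1, min(genes, cells)]")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc, nu = n_components, nv = n_components)
  total <- sum(xc^2)
  if (total == 0) total <- 1
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u * rep(d, each = nrow(xc))
  rotation <- sv$v
  # sign convention: largest-|loading| positive per component
  for (k in seq_len(n_components)) {
    i <- which.max(abs(rotation[, k]))
    if (rotation[i, k] < 0) {
      rotation[, k] <- -rotation[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- colnames(rotation) <-
    paste0("PC", seq_len(n_components))
  if (is.null(cell_ids)) cell_ids <- rownames(x)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(nrow(x)))
  rownames(scores) <- cell_ids
  structure(
    list(scores = scores, variance_fractions = d^2 / total,
         cell_index = cell_ids, rotation = rotation, center = center),
    class = "embedding"
  )
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d cells x %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$variance_fractions)))
  invisible(x)
}

#' Standard per-cell-type embedding pipeline
#'
#' Convenience wrapper used throughout: log-normalize, keep the `n_hvg`
#' most variable genes, scale with clipping, and run [pca()].
#'
#' @param table a [cell_table()] (already subset to the cells of interest).
#' @param n_hvg number of highly variable genes, default 2000.
#' @param n_components number of PCs, default `min(100, genes, cells - 1)`.
#' @param clip scaling clip bound.
#' @return an `embedding`.
#' @export
embed_cells <- function(table, n_hvg = 2000, n_components = NULL,
                        clip = 10) {
  norm <- lognormalize(table)
  hv <- select_hvg(norm, n_hvg)
  scaled <- scale_genes(norm[hv, , drop = FALSE], clip = clip)
  if (is.null(n_components))
    n_components <- min(100L, nrow(scaled), ncol(scaled) - 1L)
  pca(scaled, n_components, cell_ids = table$cell_meta$cell_id)
}
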