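#' Correlation-based soft classifier against reference profiles
#'
#' A fully specified stand-in for anchor-based label transfer: each query
#' cell is Pearson-correlated with every reference cell-type centroid over
#' the shared gene universe; correlations are shifted to non-negative
#' (`max(r, 0)`) and normalized to sum 1. Cells with all-zero shifted
#' correlations fall back to a uniform score vector. Downstream threshold
#' rules operate on these scores exactly as they would on imported
#' prediction scores.
#'
#' @param query genes x cells matrix of log-normalized query expression
#'   with gene-id rownames.
#' @param reference_profiles genes x cell-types matrix of reference
#'   centroids with gene-id rownames.
#' @param min_genes minimum shared gene universe, default 10.
#' @return cells x cell-types matrix of prediction scores; rows sum to 1.
#' @export
soft_classify <- function(query, reference_profiles, min_genes = 10) {
  shared <- intersect(rownames(query), rownames(reference_profiles))
  if (length(shared) < min_genes)
    stop("validation error: shared gene universe has ", length(shared),
         " genes (< ", min_genes, ")")
  q <- as.matrix(query[shared, , drop = FALSE])
  r <- as.matrix(reference_profiles[shared, , drop = FALSE])
  scores <- suppressWarnings(stats::cor(q, r))
  scores[is.na(scores)] <- 0
  scores[scores < 0] <- 0
  tot <- rowSums(scores)
  zero <- tot == 0
  scores[zero, ] <- 1 / ncol(scores)
  scores[!zero, ] <- scores[!zero, , drop = FALSE] / tot[!zero]
  rownames(scores) <- colnames(query)
  scores
}

#' Reference-atlas label assignment (single strict threshold)
#'
#' A cell is assigned its top-scoring reference type when the top score
#' strictly exceeds `threshold` (0.6), otherwise left unassigned.
#'
#' @param scores cells x types prediction-score matrix.
#' @param threshold strict top-score threshold, default 0.6.
#' @return character vector of labels, `"unassigned"` where no type wins.
#' @export
assign_labels_reference <- function(scores, threshold = 0.6) {
  top <- max.col(scores, ties.method = "first")
  best <- scores[cbind(seq_len(nrow(scores)), top)]
  out <- ifelse(best > threshold, colnames(scores)[top], "unassigned")
  stats::setNames(out, rownames(scores))
}

#' Across-age label assignment (two-tier rule)
#'
#' A cell is assigned its top type when the top score strictly exceeds
#' `hi` (0.8); failing that, it is still assigned when the top score
#' strictly exceeds `lo` (0.5) *and* is at least `ratio` (2) times the
#' second-best score. Otherwise unassigned.
#'
#' @param scores cells x types prediction-score matrix.
#' @param hi,lo strict top-score thresholds (0.8 / 0.5).
#' @param ratio inclusive top-to-second-best ratio requirement (2).
#' @return character vector of labels, `"unassigned"` where no rule fires.
#' @export
assign_labels_acrossage <- function(scores, hi = 0.8, lo = 0.5,
                                    ratio = 2) {
  n <- nrow(scores)
  top <- max.col(scores, ties.method = "first")
  best <- scores[cbind(seq_len(n), top)]
  second <- vapply(seq_len(n), function(i) {
    max(scores[i, -top[i]])
  }, 0)
  ok <- best > hi | (best > lo & best >= ratio * second)
  out <- ifelse(ok, colnames(scores)[top], "unassigned")
  stats::setNames(out, rownames(scores))
}

#' Prediction matrix: mean scores per query cell type
#'
#' @param scores cells x reference-types prediction-score matrix.
#' @param query_types per-cell query cell-type labels.
#' @return query-types x reference-types matrix of mean scores (empty
#'   query types omitted).
#' @export
prediction_matrix <- function(scores, query_types) {
  query_types <- as.character(query_types)
  lv <- sort(unique(query_types))
  out <- t(vapply(lv, function(q) {
    colMeans(scores[query_types == q, , drop = FALSE])
  }, numeric(ncol(scores))))
  rownames(out) <- lv
  out
}

#' Identity ratio of a query cell type
#'
#' (diagonal - top off-diagonal) / diagonal of the averaged prediction
#' matrix: 1 means complete one-to-one mapping, 0 a tie with another type,
#' negative values mean another type scores higher. `NA` when the diagonal
#' is 0.
#'
#' @param matrix prediction matrix from [prediction_matrix()].
#' @param row query type name (must also name a reference column).
#' @return numeric scalar `<= 1`, or `NA`.
#' @export
identity_ratio <- function(matrix, row) {
  if (!(row %in% rownames(matrix)) || !(row %in% colnames(matrix)))
    stop("row must name both a query row and a reference column")
  d <- matrix[row, row]
  if (d == 0) {
    warning("identity ratio undefined: zero diagonal for ", row)
    return(NA_real_)
  }
  off <- matrix[row, setdiff(colnames(matrix), row)]
  top_off <- if (length(off)) max(off) else 0
  (d - top_off) / d
}

#' Identity ratios for every matched query type
#'
#' @param matrix prediction matrix whose row names also appear as columns.
#' @return named numeric vector of identity ratios.
#' @export
identity_ratios <- function(matrix) {
  rows <- intersect(rownames(matrix), colnames(matrix))
  vapply(rows, function(r) suppressWarnings(identity_ratio(matrix, r)), 0)
}
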