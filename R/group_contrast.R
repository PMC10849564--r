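#' Per-sample centroids in an embedding
#'
#' @param embedding an `embedding` or cells x components score matrix.
#' @param sample_ids per-cell sample labels.
#' @return samples x components matrix of coordinate-wise means, rows named
#'   by sample.
#' @export
sample_centroids <- function(embedding, sample_ids) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  sample_ids <- as.character(sample_ids)
  ids <- sort(unique(sample_ids))
  cents <- vapply(ids, function(s) {
    colMeans(scores[sample_ids == s, , drop = FALSE])
  }, numeric(ncol(scores)))
  # vapply drops to a vector when the space is 1-dimensional
  out <- if (is.matrix(cents)) t(cents) else matrix(cents, ncol = 1)
  rownames(out) <- ids
  out
}

#' Inter/intra-group centroid-distance statistic
#'
#' Manhattan distances between all pairs of sample centroids. The effect
#' size is the mean between-group distance divided by the mean within-group
#' distance (pooled over both groups); the p-value is a two-sided
#' two-sample t-test between the between-group and within-group distance
#' lists. When all distances are zero the ratio is 1 with p = 1; when only
#' the within-group mean is zero the ratio is flagged infinite.
#'
#' @param centroids samples x dims matrix from [sample_centroids()].
#' @param group per-sample group labels (exactly 2 levels, >= 2 samples
#'   each).
#' @param n_perm optional number of label permutations for a permutation
#'   p-value on the ratio (0 = off).
#' @return list with `ratio`, `p_raw`, `n_between`, `n_within`,
#'   `degenerate` flag and optionally `p_perm`.
#' @export
group_distance_statistic <- function(centroids, group, n_perm = 0) {
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) != 2L) stop("exactly two groups required")
  if (any(table(group) < 2L)) stop("need >= 2 samples per group")
  d <- as.matrix(stats::dist(centroids, method = "manhattan"))
  n <- nrow(d)
  pair_i <- which(upper.tri(d))
  same <- outer(group, group, `==`)[pair_i]
  dv <- d[pair_i]
  stat <- function(same) {
    between <- dv[!same]
    within <- dv[same]
    mb <- mean(between); mw <- mean(within)
    if (mw == 0) if (mb == 0) 1 else Inf else mb / mw
  }
  between <- dv[!same]
  within <- dv[same]
  degenerate <- FALSE
  if (mean(within) == 0 && mean(between) == 0) {
    ratio <- 1; p <- 1; degenerate <- TRUE
  } else {
    ratio <- stat(same)
    if (stats::var(between) + stats::var(within) == 0) {
      p <- 1; degenerate <- TRUE
    } else {
      p <- stats::t.test(between, within)$p.value
    }
  }
  out <- list(ratio = ratio, p_raw = p, n_between = length(between),
              n_within = length(within), degenerate = degenerate)
  if (n_perm > 0) {
    obs <- ratio
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gp <- sample(group)
      sp <- outer(gp, gp, `==`)[pair_i]
      if (stat(sp) >= obs) hits <- hits + 1L
    }
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, capped at 1. `NA` entries are passed through.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted vector of the same length.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1))
    stop("validation error: p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Group contrasts for every cell type
#'
#' Per cell type: subset the cells, log-normalize, keep 2000 highly
#' variable genes, scale, PCA (up to 100 PCs), select the PC count
#' explaining 20% of variance, compute per-sample centroids and the
#' inter/intra Manhattan distance statistic. BH adjustment is applied
#' across cell types. Cell types without >= 2 samples per group are
#' skipped with a warning.
#'
#' @param table a [cell_table()].
#' @param group_field metadata column defining the two groups (`"sex"` or
#'   `"genotype"`).
#' @param cell_types cell types to test (default all assigned).
#' @param ages optional age subset applied before testing.
#' @param min_cells_per_sample samples with fewer cells of the type are
#'   dropped from that type's centroid set (default 1).
#' @param n_hvg,pc_target,pc_cap embedding parameters.
#' @return data.frame with columns `cell_type`, `ratio`, `p_raw`, `p_adj`,
#'   `n_samples_a`, `n_samples_b`, `n_pcs_used`, `degenerate`.
#' @export
contrast_all_celltypes <- function(table, group_field = "sex",
                                   cell_types = NULL, ages = NULL,
                                   min_cells_per_sample = 1,
                                   n_hvg = 2000, pc_target = 0.20,
                                   pc_cap = 100) {
  meta <- table$cell_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(ages)) keep <- meta$age %in% ages
  if (is.null(cell_types))
    cell_types <- setdiff(sort(unique(meta$cell_type)), "unassigned")
  rows <- lapply(cell_types, function(ctype) {
    idx <- which(keep & meta$cell_type == ctype)
    if (!length(idx)) return(NULL)
    sub <- subset_cells(table, idx)
    cnt <- table(sub$cell_meta$sample_id)
    good <- names(cnt)[cnt >= min_cells_per_sample]
    sub <- subset_cells(sub, sub$cell_meta$sample_id %in% good)
    grp_of <- tapply(sub$cell_meta[[group_field]],
                     sub$cell_meta$sample_id, `[`, 1L)
    if (length(unique(grp_of)) != 2L || any(table(grp_of) < 2L)) {
      warning("skipping cell type ", ctype,
              ": needs >= 2 samples in each of 2 groups")
      return(NULL)
    }
    emb <- embed_cells(sub, n_hvg = n_hvg,
                       n_components = min(pc_cap, n_genes(sub),
                                          n_cells(sub) - 1L))
    n_pcs <- select_pc_count(emb$variance_fractions, pc_target, pc_cap)
    cents <- sample_centroids(emb$scores[, seq_len(n_pcs), drop = FALSE],
                              sub$cell_meta$sample_id)
    gs <- group_distance_statistic(cents,
                                   grp_of[rownames(cents)])
    tab <- table(grp_of)
    data.frame(cell_type = ctype, ratio = gs$ratio, p_raw = gs$p_raw,
               n_samples_a = as.integer(tab[1L]),
               n_samples_b = as.integer(tab[2L]),
               n_pcs_used = n_pcs, degenerate = gs$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_adj <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  out[, c("cell_type", "ratio", "p_raw", "p_adj", "n_samples_a",
          "n_samples_b", "n_pcs_used", "degenerate")]
}

#' Pseudobulk aggregation by sample
#'
#' Sums raw counts across all cells of each sample; the grand total is
#' conserved. Empty samples are absent.
#'
#' @param table a [cell_table()].
#' @return genes x samples integer matrix (dense), columns sorted by
#'   sample id.
#' @export
pseudobulk <- function(table) {
  ids <- sort(unique(table$cell_meta$sample_id))
  out <- vapply(ids, function(s) {
    Matrix::rowSums(table$counts[, table$cell_meta$sample_id == s,
                                 drop = FALSE])
  }, numeric(n_genes(table)))
  rownames(out) <- table$gene_ids
  out
}

# log2 counts-per-million with +1 pseudocount, per column
log_cpm <- function(pb) {
  libs <- colSums(pb)
  libs[libs == 0] <- 1
  log2(sweep(pb, 2L, libs, `/`) * 1e6 + 1)
}

#' Pseudobulk differential expression (one-way F-test)
#'
#' The in-house engine standing in for moderated pipelines: pseudobulk
#' counts are transformed to log2-CPM (+1 pseudocount) and each gene is
#' tested with a one-way F-test across the group labels (equivalent to a
#' two-sided t-test for two groups), followed by BH adjustment. Genes in
#' `exclude` are dropped before testing; zero-residual-variance genes get
#' p = 1 with a flag.
#'
#' @param pb genes x samples pseudobulk matrix with gene-id rownames.
#' @param groups per-sample group labels (>= 2 samples per group).
#' @param exclude character vector (or list of vectors) of gene ids to
#'   remove before testing (e.g. mitochondrial, ribosomal, Y, X-inactivation
#'   lists for sex contrasts).
#' @param alpha significance threshold on adjusted p, default 0.05.
#' @return data.frame `de_result`: `gene_id`, per-group means, `delta`
#'   (second minus first group mean, 2-group case), `stat`, `p_raw`,
#'   `p_adj`, `sign`, `flat` (zero-residual-variance flag), `significant`.
#' @export
de_test <- function(pb, groups, exclude = character(0), alpha = 0.05) {
  exclude <- unique(unlist(exclude))
  if (length(exclude)) pb <- pb[!(rownames(pb) %in% exclude), ,
                                drop = FALSE]
  groups <- as.character(groups)
  if (length(groups) != ncol(pb))
    stop("groups must align with pseudobulk columns")
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 samples in each of >= 2 groups")
  x <- log_cpm(pb)
  lv <- names(tab)
  k <- length(lv)
  n <- ncol(x)
  gm <- rowMeans(x)
  means <- vapply(lv, function(g) rowMeans(x[, groups == g, drop = FALSE]),
                  numeric(nrow(x)))
  ssb <- as.vector(means^2 %*% as.vector(tab)) - n * gm^2
  ssb <- pmax(ssb, 0)
  sst <- rowSums(x^2) - n * gm^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  flat <- ssw <= 1e-12
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[flat & ssb <= 1e-12] <- 1  # constant gene: never significant
  p[flat & ssb > 1e-12] <- 0   # perfect separation
  out <- data.frame(gene_id = rownames(x), stringsAsFactors = FALSE)
  colnames(means) <- paste0("mean_", lv)
  out <- cbind(out, means)
  out$delta <- if (k == 2L) means[, 2L] - means[, 1L] else NA_real_
  out$stat <- f
  out$p_raw <- p
  out$p_adj <- bh_adjust(p)
  out$sign <- if (k == 2L) sign(out$delta) else NA_real_
  out$flat <- flat
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Per-sample cell-type proportions
#'
#' @param table a [cell_table()].
#' @return samples x cell-types matrix of fractions; rows sum to 1.
#' @export
celltype_proportions <- function(table) {
  tab <- table(table$cell_meta$sample_id, table$cell_meta$cell_type)
  out <- as.matrix(tab)
  out / rowSums(out)
}
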