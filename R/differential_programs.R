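#' Developmental differential expression within one cell type (devDEGs)
#'
#' Cells of the cell type are pseudobulked per sample; log2-CPM profiles
#' are tested per gene with a one-way F-test across age groups and BH
#' adjusted. devDEGs are genes with adjusted p below `alpha` (FDR < 5%).
#'
#' @param table a [cell_table()].
#' @param cell_type cell type to test.
#' @param ages optional age subset (default all ages present); at least 2
#'   ages with >= 2 samples each are required overall.
#' @param exclude gene ids dropped before testing.
#' @param alpha FDR threshold, default 0.05.
#' @return a `de_result` data.frame (see [de_test()]) with attribute
#'   `cell_type`.
#' @export
dev_de <- function(table, cell_type, ages = NULL,
                   exclude = character(0), alpha = 0.05) {
  sub <- subset_cells(table, table$cell_meta$cell_type == cell_type)
  if (!is.null(ages)) sub <- subset_cells(sub, sub$cell_meta$age %in% ages)
  pb <- pseudobulk(sub)
  age_of <- tapply(sub$cell_meta$age, sub$cell_meta$sample_id, `[`, 1L)
  groups <- age_of[colnames(pb)]
  if (length(unique(groups)) < 2L)
    stop("need samples at >= 2 ages for ", cell_type)
  out <- de_test(pb, groups, exclude = exclude, alpha = alpha)
  attr(out, "cell_type") <- cell_type
  out
}

#' Sharing classification of devDEGs across cell types
#'
#' A gene called in more than 70% of cell types is `shared`, in fewer than
#' 20% `specific`, otherwise `intermediate` (both boundaries strict).
#'
#' @param devdeg_sets named list: per cell type, the character vector of
#'   its devDEG gene ids.
#' @param n_celltypes total number of cell types tested (defaults to
#'   `length(devdeg_sets)`).
#' @param shared_cut,specific_cut the strict fraction cutoffs (0.7 / 0.2).
#' @return data.frame `gene_id`, `n_called`, `fraction`, `label`.
#' @export
classify_sharing <- function(devdeg_sets,
                             n_celltypes = length(devdeg_sets),
                             shared_cut = 0.7, specific_cut = 0.2) {
  if (n_celltypes <= 0) stop("n_celltypes must be positive")
  genes <- sort(unique(unlist(devdeg_sets)))
  n_called <- vapply(genes, function(g) {
    sum(vapply(devdeg_sets, function(s) g %in% s, TRUE))
  }, 0L)
  f <- n_called / n_celltypes
  label <- ifelse(f > shared_cut, "shared",
                  ifelse(f < specific_cut, "specific", "intermediate"))
  data.frame(gene_id = genes, n_called = n_called, fraction = f,
             label = label, stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a smooth expression trend over the age axis
#'
#' Penalized cubic smoothing spline on the age-index axis with fixed
#' degrees of freedom, evaluated at every ladder age. Constant input
#' returns a constant trend. Requires at least `df + 1` distinct ages.
#'
#' @param values per-sample expression values.
#' @param ages per-sample age labels.
#' @param ladder an [age_ladder()].
#' @param df spline degrees of freedom, default 4.
#' @return named numeric trend vector over the ladder's labels.
#' @export
fit_trend <- function(values, ages, ladder, df = 4) {
  x <- age_index(ladder, ages)
  grid <- seq_along(ladder$labels)
  if (length(unique(x)) < df + 1)
    stop("validation error: need >= df + 1 distinct ages")
  if (stats::var(values) == 0) {
    return(stats::setNames(rep(values[1L], length(grid)), ladder$labels))
  }
  fit <- stats::smooth.spline(x, values, df = df, cv = FALSE)
  stats::setNames(stats::predict(fit, grid)$y, ladder$labels)
}

# row-wise z-scoring with zero-variance guard (population of the row)
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  out <- (m - mu) / ifelse(sd > 0, sd, 1)
  out[sd == 0, ] <- 0
  out
}

#' Hierarchical clustering of z-scored trends
#'
#' Trends are z-scored per row and clustered agglomeratively with Ward
#' linkage on Euclidean distances, cut at `n_clusters`.
#'
#' @param trends numeric matrix, one trend per row.
#' @param n_clusters number of clusters.
#' @return integer cluster labels, one per row.
#' @export
cluster_trends <- function(trends, n_clusters) {
  trends <- as.matrix(trends)
  if (nrow(trends) < n_clusters)
    stop("need at least n_clusters trends")
  z <- zscore_rows(trends)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  stats::cutree(hc, k = n_clusters)
}

#' Gene-set module score with binned control genes
#'
#' Per cell: mean log-normalized expression of the set genes minus the
#' mean over control genes, where `n_ctrl` controls per set gene are drawn
#' (seeded, with replacement) from the same average-expression bin out of
#' `n_bins` bins. Unresolvable set ids are dropped with a warning.
#'
#' @param norm_matrix genes x cells log-normalized matrix with gene-id
#'   rownames.
#' @param gene_set character vector of gene ids.
#' @param n_bins number of average-expression bins, default 24.
#' @param n_ctrl control genes drawn per set gene, default 100.
#' @param seed integer RNG seed for the control draw.
#' @return numeric per-cell score vector.
#' @export
module_score <- function(norm_matrix, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  ids <- rownames(norm_matrix)
  if (is.null(ids)) stop("norm_matrix needs gene-id rownames")
  set <- intersect(gene_set, ids)
  if (!length(set))
    stop("validation error: gene set resolves to no genes")
  if (length(set) < length(gene_set))
    warning(length(gene_set) - length(set), " set gene(s) not found")
  avg <- Matrix::rowMeans(norm_matrix)
  n_bins <- min(n_bins, length(avg))
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  set_idx <- match(set, ids)
  ctrl <- unlist(lapply(set_idx, function(i) {
    pool <- which(bin == bin[i])
    pool <- setdiff(pool, set_idx)  # controls come from non-set bin-mates
    if (!length(pool)) pool <- which(bin == bin[i])
    pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
  }))
  set_mean <- Matrix::colMeans(norm_matrix[match(set, ids), ,
                                           drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm_matrix[ctrl, , drop = FALSE])
  unname(set_mean - ctrl_mean)
}

#' Per-age z-scored mean of a per-cell score
#'
#' Scores are averaged among cells within each age and the resulting
#' per-age vector is z-scored across ages (all-zero when constant).
#'
#' @param scores numeric per-cell scores.
#' @param ages per-cell age labels.
#' @param ladder optional [age_ladder()] fixing the age order (default:
#'   sorted unique labels).
#' @return named per-age z-score vector.
#' @export
aggregate_score_by_age <- function(scores, ages, ladder = NULL) {
  ages <- as.character(ages)
  labs <- if (is.null(ladder)) sort(unique(ages)) else
    intersect(ladder$labels, unique(ages))
  if (length(labs) < 2L)
    stop("validation error: need >= 2 ages to z-score")
  mu <- vapply(labs, function(a) mean(scores[ages == a]), 0)
  s <- stats::sd(mu)
  z <- if (is.na(s) || s == 0) rep(0, length(mu)) else (mu - mean(mu)) / s
  stats::setNames(z, labs)
}

#' Gene ids with any expression in a cell type
#'
#' A (gene, cell type) combination counts as expressed when its pseudobulk
#' count is nonzero at at least one age.
#'
#' @param table a [cell_table()].
#' @param cell_type cell type name.
#' @return character vector of expressed gene ids.
#' @export
expressed_genes <- function(table, cell_type) {
  sub <- subset_cells(table, table$cell_meta$cell_type == cell_type)
  table$gene_ids[Matrix::rowSums(sub$counts) > 0]
}

#' Refinement score of a signaling gene set
#'
#' Fraction of expressed (gene, cell type) combinations in the set whose
#' expression changes significantly between the young reference age and
#' the adult: numerator = significant combos in the dedicated two-age
#' contrast, denominator = combos with nonzero pseudobulk at >= 1 age.
#'
#' @param dev_results named list (per cell type) of `de_result` tables
#'   from the two-age contrast (e.g. [dev_de()] with
#'   `ages = c("P10", "P65")`).
#' @param gene_set character vector of gene ids.
#' @param expressed named list (per cell type) of expressed gene ids, as
#'   from [expressed_genes()].
#' @return list with `score` in `[0, 1]` (`NA` when no combo is
#'   expressed), `n_significant`, `n_expressed`.
#' @export
refinement_score <- function(dev_results, gene_set, expressed) {
  cts <- names(dev_results)
  stopifnot(!is.null(cts), all(cts %in% names(expressed)))
  n_sig <- 0L
  n_exp <- 0L
  for (ctype in cts) {
    de <- dev_results[[ctype]]
    exp_set <- intersect(gene_set, expressed[[ctype]])
    n_exp <- n_exp + length(exp_set)
    sig <- de$gene_id[de$significant]
    n_sig <- n_sig + length(intersect(exp_set, sig))
  }
  score <- if (n_exp == 0) NA_real_ else n_sig / n_exp
  list(score = score, n_significant = n_sig, n_expressed = n_exp)
}

#' Refinement score computed end-to-end from a cell table
#'
#' Convenience wrapper: per cell type, runs the young-vs-adult pseudobulk
#' contrast and collects expressed genes, then scores the set.
#'
#' @param table a [cell_table()].
#' @param gene_set character vector of gene ids.
#' @param cell_types cell types to include (default all assigned).
#' @param young_age the young reference age (e.g. `"P10"`).
#' @param adult_age the adult age (default the ladder's adult).
#' @param alpha FDR threshold, default 0.05.
#' @return as [refinement_score()].
#' @export
refinement_score_for_set <- function(table, gene_set, cell_types = NULL,
                                     young_age, adult_age = NULL,
                                     alpha = 0.05) {
  if (is.null(adult_age)) adult_age <- table$ladder$adult
  if (is.null(cell_types))
    cell_types <- setdiff(sort(unique(table$cell_meta$cell_type)),
                          "unassigned")
  devs <- lapply(cell_types, function(ctype) {
    dev_de(table, ctype, ages = c(young_age, adult_age), alpha = alpha)
  })
  names(devs) <- cell_types
  expr <- lapply(cell_types, function(ctype) expressed_genes(table, ctype))
  names(expr) <- cell_types
  refinement_score(devs, gene_set, expr)
}

#' Read a gene-set catalog from a two-column TSV
#'
#' @param path TSV with header columns `set_name`, `gene_id`.
#' @param universe optional gene-id universe; unresolvable ids are dropped
#'   with a message.
#' @return named list of character gene-id vectors.
#' @export
read_gene_sets <- function(path, universe = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("set_name", "gene_id") %in% names(df)))
  sets <- split(df$gene_id, df$set_name)
  if (!is.null(universe)) {
    sets <- lapply(sets, function(s) {
      bad <- setdiff(s, universe)
      if (length(bad))
        message(length(bad), " unresolvable id(s) dropped from a set")
      intersect(s, universe)
    })
  }
  sets
}
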