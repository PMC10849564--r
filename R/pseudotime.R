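#' Reference PC space for pseudotime
#'
#' Fits the 20-PC maturation space on reference-genotype cells of one cell
#' type: log-normalization, 2000 highly variable genes, scaling, PCA. The
#' gene selection, scaling statistics and PC basis are retained so other
#' cells (mutants) can be projected into the identical space.
#'
#' @param table a [cell_table()].
#' @param cell_type cell type to model.
#' @param reference_genotype genotype defining the reference cells.
#' @param n_hvg highly variable genes, default 2000.
#' @param n_components PC count, default 20.
#' @param clip scaling clip bound.
#' @return object of class `reference_space`: `embedding`, `genes`
#'   (selected ids), `center`/`scale` (per-gene scaling), `clip`,
#'   `pca_center`, `rotation`, `ladder`, `cell_type`,
#'   `reference_genotype`.
#' @export
build_reference_space <- function(table, cell_type, reference_genotype,
                                  n_hvg = 2000, n_components = 20,
                                  clip = 10) {
  idx <- which(table$cell_meta$cell_type == cell_type &
                 table$cell_meta$genotype == reference_genotype)
  sub <- subset_cells(table, idx)
  if (length(unique(sub$cell_meta$age)) < 2L)
    stop("validation error: reference cells must span >= 2 ages")
  if (n_cells(sub) <= n_components)
    stop("validation error: too few reference cells")
  norm <- lognormalize(sub)
  hv <- select_hvg(norm, n_hvg)
  scaled <- scale_genes(norm[hv, , drop = FALSE], clip = clip)
  n_components <- min(n_components, nrow(scaled), n_cells(sub) - 1L)
  emb <- pca(scaled, n_components, cell_ids = sub$cell_meta$cell_id)
  structure(
    list(embedding = emb, genes = sub$gene_ids[hv],
         center = attr(scaled, "center"), scale = attr(scaled, "scale"),
         clip = clip, pca_center = emb$center, rotation = emb$rotation,
         ladder = table$ladder, cell_type = cell_type,
         reference_genotype = reference_genotype,
         reference_ages = sub$cell_meta$age),
    class = "reference_space"
  )
}

#' Project cells into a fitted reference space
#'
#' Applies the reference gene selection, scaling parameters (with the same
#' clip) and PC rotation to new cells; projecting the reference cells
#' themselves reproduces their scores.
#'
#' @param space a `reference_space`.
#' @param table a [cell_table()] holding the cells to project (already
#'   subset as desired).
#' @return cells x components score matrix in the reference space.
#' @export
project_into_space <- function(space, table) {
  norm <- lognormalize(table)
  gi <- match(space$genes, table$gene_ids)
  if (anyNA(gi)) stop("table lacks reference space gene(s)")
  scaled <- scale_genes(norm[gi, , drop = FALSE], clip = space$clip,
                        center = space$center, scale = space$scale)
  x <- t(scaled)  # cells x genes
  xc <- sweep(x, 2L, space$pca_center)
  scores <- xc %*% space$rotation
  rownames(scores) <- table$cell_meta$cell_id
  scores
}

#' Principal path through age centroids
#'
#' Piecewise-linear path visiting the per-age centroids of the reference
#' embedding in ladder order; arc length is Euclidean. This deterministic
#' path stands in for a fitted principal curve: with a single lineage over
#' ordered ages the two coincide in spirit.
#'
#' @param embedding an `embedding` or score matrix of reference cells.
#' @param ages per-cell age labels.
#' @param ladder an [age_ladder()]; every label needs >= 1 cell.
#' @return object of class `principal_path`: `centroids` (ages x dims),
#'   `cum_length` (arc-length position of each centroid, starting at 0),
#'   `total_length`.
#' @export
principal_path <- function(embedding, ages, ladder) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  ages <- as.character(ages)
  cents <- vapply(ladder$labels, function(a) {
    i <- which(ages == a)
    if (!length(i)) stop("age ", a, " has no reference cells")
    colMeans(scores[i, , drop = FALSE])
  }, numeric(ncol(scores)))
  cents <- if (is.matrix(cents)) t(cents) else matrix(cents, ncol = 1)
  rownames(cents) <- ladder$labels
  seg <- sqrt(rowSums((cents[-1L, , drop = FALSE] -
                         cents[-nrow(cents), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  structure(
    list(centroids = cents, cum_length = stats::setNames(cum,
                                                         ladder$labels),
         total_length = unname(cum[length(cum)])),
    class = "principal_path"
  )
}

#' Pseudotime of cells along a principal path
#'
#' Each cell's pseudotime is the arc-length position of its nearest point
#' on the path: orthogonal projection onto every segment, clamped to the
#' segment, taking the globally nearest (ties resolved toward the earlier
#' segment). Values lie in `[0, total_length]`.
#'
#' @param path a `principal_path`.
#' @param cells cells x dims coordinate matrix in the same space.
#' @return numeric per-cell pseudotime vector.
#' @export
project_cells <- function(path, cells) {
  cells <- as.matrix(cells)
  cents <- path$centroids
  n_seg <- nrow(cents) - 1L
  best_d2 <- rep(Inf, nrow(cells))
  best_pt <- rep(0, nrow(cells))
  for (s in seq_len(n_seg)) {
    a <- cents[s, ]
    v <- cents[s + 1L, ] - a
    len2 <- sum(v^2)
    offs <- sweep(cells, 2L, a)
    t <- if (len2 > 0) pmin(1, pmax(0, (offs %*% v) / len2)) else
      rep(0, nrow(cells))
    proj <- outer(drop(t), v)
    d2 <- rowSums((offs - proj)^2)
    better <- d2 < best_d2  # strict: ties stay on the earlier segment
    best_pt[better] <- path$cum_length[s] +
      drop(t)[better] * sqrt(len2)
    best_d2[better] <- d2[better]
  }
  unname(best_pt)
}

#' Developmental-delay test on pseudotime
#'
#' Pseudotimes are averaged within samples; the two genotypes' per-sample
#' means are compared with a two-sided t-test. Zero pooled variance gives
#' p = 1 with a flag.
#'
#' @param pt per-cell pseudotime.
#' @param samples per-cell sample labels.
#' @param genotypes per-cell genotype labels (exactly 2 levels with >= 2
#'   samples each).
#' @return object of class `pseudotime_result`: `sample_means` data.frame,
#'   `group_means`, `difference` (second minus first level,
#'   alphabetical), `p_value`, `degenerate`.
#' @export
delay_test <- function(pt, samples, genotypes) {
  samples <- as.character(samples)
  genotypes <- as.character(genotypes)
  sm <- tapply(pt, samples, mean)
  geno_of <- tapply(genotypes, samples, `[`, 1L)[names(sm)]
  lv <- sort(unique(geno_of))
  if (length(lv) != 2L) stop("exactly two genotypes required")
  if (any(table(geno_of) < 2L)) stop("need >= 2 samples per genotype")
  x <- sm[geno_of == lv[1L]]
  y <- sm[geno_of == lv[2L]]
  degenerate <- stats::var(x) + stats::var(y) == 0
  p <- if (degenerate) 1 else stats::t.test(y, x)$p.value
  structure(
    list(sample_means = data.frame(sample_id = names(sm),
                                   genotype = unname(geno_of),
                                   mean_pseudotime = unname(sm),
                                   stringsAsFactors = FALSE),
         group_means = stats::setNames(c(mean(x), mean(y)), lv),
         difference = mean(y) - mean(x), p_value = p,
         degenerate = degenerate),
    class = "pseudotime_result"
  )
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf(
    "delay test: %s = %.3f vs %s = %.3f (diff %.3f), p = %.3g\n",
    names(x$group_means)[1L], x$group_means[1L],
    names(x$group_means)[2L], x$group_means[2L], x$difference,
    x$p_value))
  invisible(x)
}

#' End-to-end pseudotime delay analysis for one cell type
#'
#' Builds the reference 20-PC space and principal path from the reference
#' genotype's cells across all ages, projects every genotype's cells of
#' the cell type into it, and tests mutant versus control per-sample mean
#' pseudotime, optionally within an age subset.
#'
#' @param table a [cell_table()] containing both genotypes.
#' @param cell_type cell type to analyse.
#' @param reference_genotype the control genotype (also the space
#'   reference).
#' @param mutant_genotype the genotype to compare against the reference.
#' @param ages optional age subset for the delay test (the space and path
#'   always use all reference ages).
#' @param n_hvg,n_components space parameters (2000 / 20).
#' @return list with `space`, `path`, `pseudotime` (data.frame of cell,
#'   sample, genotype, age, pseudotime) and `test` (a
#'   `pseudotime_result`).
#' @export
pseudotime_delay <- function(table, cell_type, reference_genotype,
                             mutant_genotype, ages = NULL, n_hvg = 2000,
                             n_components = 20) {
  space <- build_reference_space(table, cell_type, reference_genotype,
                                 n_hvg = n_hvg,
                                 n_components = n_components)
  path <- principal_path(space$embedding, space$reference_ages,
                         table$ladder)
  keep <- table$cell_meta$cell_type == cell_type &
    table$cell_meta$genotype %in% c(reference_genotype, mutant_genotype)
  if (!is.null(ages)) keep <- keep & table$cell_meta$age %in% ages
  sub <- subset_cells(table, which(keep))
  scores <- project_into_space(space, sub)
  pt <- project_cells(path, scores)
  res <- delay_test(pt, sub$cell_meta$sample_id, sub$cell_meta$genotype)
  list(space = space, path = path,
       pseudotime = data.frame(cell_id = sub$cell_meta$cell_id,
                               sample_id = sub$cell_meta$sample_id,
                               genotype = sub$cell_meta$genotype,
                               age = sub$cell_meta$age, pseudotime = pt,
                               stringsAsFactors = FALSE),
       test = res)
}
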