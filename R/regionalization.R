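#' Mean scaled expression profile per cell type
#'
#' @param scaled_matrix genes x cells matrix of scaled values.
#' @param cell_types per-cell cell-type labels.
#' @return genes x cell-types profile matrix (columns sorted by type).
#' @export
celltype_profiles <- function(scaled_matrix, cell_types) {
  cell_types <- as.character(cell_types)
  types <- sort(unique(cell_types))
  out <- vapply(types, function(ctype) {
    rowMeans(scaled_matrix[, cell_types == ctype, drop = FALSE])
  }, numeric(nrow(scaled_matrix)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)  # single-gene input
  colnames(out) <- types
  out
}

#' Pearson correlation between cell-type profiles
#'
#' Symmetric with unit diagonal; zero-variance profiles give `NA` rows and
#' are flagged in the `degenerate` attribute.
#'
#' @param profiles genes x cell-types matrix.
#' @return cell-types x cell-types correlation matrix.
#' @export
profile_correlation <- function(profiles) {
  if (nrow(profiles) < 2L) stop("need >= 2 genes")
  sds <- apply(profiles, 2L, stats::sd)
  out <- suppressWarnings(stats::cor(profiles))
  diag(out) <- 1
  attr(out, "degenerate") <- colnames(profiles)[sds == 0]
  out
}

#' Per-age cell-type correlation matrices
#'
#' For each age: subset that age's cells, log-normalize, scale genes
#' within the age (cross-age scaling would leak age signal into region
#' correlations), average into cell-type profiles and correlate them.
#'
#' @param table a [cell_table()].
#' @param cell_types cell types to include (default all assigned).
#' @return named list over ages of correlation matrices.
#' @export
celltype_correlation_by_age <- function(table, cell_types = NULL) {
  if (is.null(cell_types))
    cell_types <- setdiff(sort(unique(table$cell_meta$cell_type)),
                          "unassigned")
  ages <- intersect(table$ladder$labels, unique(table$cell_meta$age))
  out <- lapply(ages, function(a) {
    sub <- subset_cells(table, table$cell_meta$age == a &
                          table$cell_meta$cell_type %in% cell_types)
    scaled <- scale_genes(lognormalize(sub))
    profile_correlation(celltype_profiles(scaled,
                                          sub$cell_meta$cell_type))
  })
  names(out) <- ages
  out
}

#' Within-region correlation across ages, normalized to adult
#'
#' Per age and region: the mean off-diagonal Pearson correlation among the
#' region's member cell types, divided by the same mean at the adult age.
#' Regions with fewer than 2 member types are excluded with a warning.
#'
#' @param per_age named list (over ages, adult last or included) of
#'   cell-type correlation matrices, as from
#'   [celltype_correlation_by_age()].
#' @param regions named character vector mapping cell type -> region.
#' @param adult the adult age label (must be a name of `per_age`).
#' @return data.frame `age`, `region`, `mean_correlation`, `normalized`.
#' @export
within_region_correlation <- function(per_age, regions, adult) {
  stopifnot(adult %in% names(per_age))
  region_members <- split(names(regions), unname(regions))
  scorable <- names(region_members)[vapply(region_members, length, 0L) >= 2]
  dropped <- setdiff(names(region_members), scorable)
  if (length(dropped))
    warning("excluding single-member region(s): ",
            paste(dropped, collapse = ", "))
  mean_off <- function(corr, members) {
    members <- intersect(members, rownames(corr))
    if (length(members) < 2L) return(NA_real_)
    m <- corr[members, members, drop = FALSE]
    mean(m[upper.tri(m)])
  }
  rows <- list()
  for (reg in scorable) {
    adult_val <- mean_off(per_age[[adult]], region_members[[reg]])
    for (a in names(per_age)) {
      v <- mean_off(per_age[[a]], region_members[[reg]])
      rows[[length(rows) + 1L]] <- data.frame(
        age = a, region = reg, mean_correlation = v,
        normalized = v / adult_val, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# vectorized one-vs-rest Wilcoxon rank-sum (normal approximation with tie
# correction and continuity correction, matching wilcox.test exact=FALSE)
rank_sum_test <- function(x, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  stats <- apply(x, 1L, function(v) {
    r <- rank(v)
    w <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    nt <- table(v)
    tie <- sum(nt^3 - nt)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
    c(w, sigma2)
  })
  w <- stats[1L, ]
  sigma <- sqrt(stats[2L, ])
  mu <- n1 * n2 / 2
  z <- w - mu
  z <- (z - sign(z) * 0.5) / ifelse(sigma > 0, sigma, 1)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma == 0] <- 1
  pmin(p, 1)
}

#' One-vs-rest region marker detection
#'
#' Per region, each gene's log-normalized values in the region's cells are
#' compared to all other cells with a Wilcoxon rank-sum test; p-values are
#' BH-adjusted across genes within the region, and markers are genes with
#' adjusted p below `alpha` and higher in-region mean.
#'
#' @param table a [cell_table()].
#' @param regions per-cell region labels (default the metadata `region`).
#' @param alpha adjusted-p cutoff, default 0.05.
#' @return named list (per region) of data.frames `gene_id`, `delta`
#'   (in-region minus rest mean), `p_raw`, `p_adj`, markers only.
#' @export
find_region_markers <- function(table, regions = NULL, alpha = 0.05) {
  if (is.null(regions)) regions <- table$cell_meta$region
  regions <- as.character(regions)
  lv <- setdiff(sort(unique(regions)), "unassigned")
  if (length(lv) < 2L) stop("need >= 2 regions")
  x <- as.matrix(lognormalize(table))
  out <- lapply(lv, function(reg) {
    ing <- regions == reg
    p <- rank_sum_test(x, ing)
    delta <- rowMeans(x[, ing, drop = FALSE]) -
      rowMeans(x[, !ing, drop = FALSE])
    p_adj <- bh_adjust(p)
    keep <- p_adj < alpha & delta > 0
    data.frame(gene_id = table$gene_ids[keep], delta = delta[keep],
               p_raw = p[keep], p_adj = p_adj[keep],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- lv
  out
}

#' Mean log-normalized expression per region for a marker panel
#'
#' @param table a [cell_table()] (typically one age's cells).
#' @param markers character vector of marker gene ids.
#' @param regions per-cell region labels (default metadata `region`).
#' @return regions x markers matrix of mean log-normalized expression.
#' @export
region_marker_profile <- function(table, markers, regions = NULL) {
  if (is.null(regions)) regions <- table$cell_meta$region
  x <- lognormalize(table)
  gi <- match(markers, table$gene_ids)
  if (anyNA(gi)) stop("unknown marker gene id(s)")
  lv <- setdiff(sort(unique(as.character(regions))), "unassigned")
  prof <- vapply(lv, function(reg) {
    Matrix::rowMeans(x[gi, regions == reg, drop = FALSE])
  }, numeric(length(markers)))
  out <- if (is.matrix(prof)) t(prof) else matrix(prof, ncol = 1)
  dimnames(out) <- list(lv, markers)
  out
}

#' Correlation of regional marker expression to the adult pattern
#'
#' Per age, the region x marker mean-expression matrix is flattened and
#' Pearson-correlated with the adult age's matrix.
#'
#' @param table a [cell_table()].
#' @param adult_markers character vector of adult regional marker ids.
#' @return named per-age correlation vector (1 at the adult age).
#' @export
marker_correlation_to_adult <- function(table, adult_markers) {
  if (!length(adult_markers)) stop("adult markers must be nonempty")
  ages <- intersect(table$ladder$labels, unique(table$cell_meta$age))
  profs <- lapply(ages, function(a) {
    region_marker_profile(subset_cells(table, table$cell_meta$age == a),
                          adult_markers)
  })
  names(profs) <- ages
  adult <- as.vector(profs[[table$ladder$adult]])
  vapply(profs, function(p) stats::cor(as.vector(p), adult), 0)
}
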