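#' Number of PCs explaining a target variance fraction
#'
#' The smallest k whose cumulative variance fraction reaches `target`
#' (default 20% of the variance in the data); if more than `cap` PCs would
#' be needed (or the target is never reached), `cap` is used, bounded by
#' the number of components available.
#'
#' @param variance_fractions nonincreasing vector of per-PC variance
#'   fractions.
#' @param target cumulative variance target, default 0.20.
#' @param cap maximum number of PCs, default 100.
#' @return integer PC count.
#' @export
select_pc_count <- function(variance_fractions, target = 0.20, cap = 100) {
  if (!length(variance_fractions))
    stop("validation error: empty variance fractions")
  k <- which(cumsum(variance_fractions) >= target)
  if (!length(k) || k[1L] > cap) min(cap, length(variance_fractions))
  else k[1L]
}

#' Manhattan distance from each age centroid to the adult centroid
#'
#' Per-age centroids are coordinate-wise means over that age's cells in PC
#' space; the trajectory value at an age is the Manhattan (L1) distance
#' between that centroid and the adult centroid. Ages with no cells are
#' returned as `NA` and excluded from staging downstream.
#'
#' @param embedding an `embedding` (or a cells x components score matrix).
#' @param ages per-cell age labels aligned with the embedding rows.
#' @param ladder an [age_ladder()]; its adult age must have cells.
#' @param n_pcs optional number of leading PCs to use (default all).
#' @return named numeric vector over the ladder's labels; adult entry 0.
#' @export
distance_trajectory <- function(embedding, ages, ladder, n_pcs = NULL) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  if (!is.null(n_pcs)) scores <- scores[, seq_len(n_pcs), drop = FALSE]
  ages <- as.character(ages)
  if (length(ages) != nrow(scores))
    stop("ages must align with embedding rows")
  if (!any(ages == ladder$adult))
    stop("no cells at the adult age ", ladder$adult)
  cents <- lapply(ladder$labels, function(a) {
    i <- which(ages == a)
    if (!length(i)) return(NULL)
    colMeans(scores[i, , drop = FALSE])
  })
  adult <- cents[[length(cents)]]
  out <- vapply(cents, function(ct) {
    if (is.null(ct)) NA_real_ else sum(abs(ct - adult))
  }, 0)
  names(out) <- ladder$labels
  out
}

#' Monotone clamping of a distance trajectory
#'
#' Left-to-right scan over ages: whenever a value exceeds the previous
#' clamped value, it is replaced by that previous value (the first value is
#' unchanged). This removes transient movement away from the adult state so
#' the curve reads as cumulative maturation. `NA` entries are carried
#' through without updating the running value.
#'
#' @param raw numeric vector over ordered ages.
#' @return clamped vector, never exceeding `raw` anywhere.
#' @export
clamp_monotone <- function(raw) {
  out <- raw
  prev <- NA_real_
  for (i in seq_along(out)) {
    if (is.na(out[i])) next
    if (!is.na(prev) && out[i] > prev) out[i] <- prev
    prev <- out[i]
  }
  out
}

#' Maturation accrued in each stage
#'
#' Stage delta = clamped distance at the stage's earlier age minus at its
#' later age (non-negative by clamping). Stages touching an age with no
#' cells get `NA`.
#'
#' @param clamped named clamped distance vector over the ladder's labels.
#' @param ladder an [age_ladder()].
#' @return named non-negative vector, one entry per stage.
#' @export
stage_deltas <- function(clamped, ladder) {
  d <- clamped[ladder$stage_from] - clamped[ladder$stage_to]
  names(d) <- ladder$stage_names
  d
}

#' Classify a trajectory as gradual / intermediate / stepwise
#'
#' k* is the minimum number of stages, taken largest-first, whose summed
#' deltas reach `threshold` (90%) of the total change. With five stages,
#' k* of 4-5 is gradual (class 1), 3 is intermediate (class 2) and 1-2 is
#' stepwise (class 3). For S != 5 stages the fractional cutpoints k*/S <=
#' 0.4 (class 3) and <= 0.6 (class 2) are used, which reduce to the 2/3/4-5
#' split at S = 5.
#'
#' @param stage_deltas non-negative per-stage deltas (`NA` stages dropped).
#' @param threshold maturation fraction defining k*, default 0.9.
#' @return integer class 1, 2 or 3; `NA` (with a warning) when the total
#'   change is zero.
#' @export
classify_trajectory <- function(stage_deltas, threshold = 0.9) {
  d <- stage_deltas[!is.na(stage_deltas)]
  if (any(d < 0)) stop("stage deltas must be non-negative")
  total <- sum(d)
  if (total == 0) {
    warning("zero total change: trajectory class undefined")
    return(NA_integer_)
  }
  s <- length(d)
  cum <- cumsum(sort(d, decreasing = TRUE))
  k_star <- which(cum >= threshold * total)[1L]
  frac <- k_star / s
  if (frac <= 0.4) 3L else if (frac <= 0.6) 2L else 1L
}

#' Full maturation trajectory for one cell type
#'
#' Runs the standard per-cell-type pipeline: subset the cells, log-
#' normalize, keep the 2000 most variable genes, scale, PCA, select the PC
#' count explaining 20% of variance (capped at 100), compute the Manhattan
#' centroid-distance trajectory to the adult centroid, clamp it monotone,
#' derive stage deltas and the trajectory class.
#'
#' @param table a [cell_table()].
#' @param cell_type cell-type name to analyse.
#' @param n_hvg,pc_target,pc_cap pipeline parameters (2000 / 0.20 / 100).
#' @param cells optional logical mask over the table's cells applied before
#'   the cell-type subset (e.g. one sex).
#' @return object of class `trajectory`: `cell_type`, `ladder`,
#'   `raw_distance`, `clamped_distance`, `stage_deltas`, `total_change`,
#'   `class_label`, `n_pcs_used`, `n_cells`.
#' @export
maturation_trajectory <- function(table, cell_type, n_hvg = 2000,
                                  pc_target = 0.20, pc_cap = 100,
                                  cells = NULL) {
  keep <- table$cell_meta$cell_type == cell_type
  if (!is.null(cells)) keep <- keep & cells
  sub <- subset_cells(table, which(keep))
  if (n_cells(sub) < 2) stop("cell type ", cell_type, " has < 2 cells")
  emb <- embed_cells(sub, n_hvg = n_hvg,
                     n_components = min(pc_cap, n_genes(sub),
                                        n_cells(sub) - 1L))
  n_pcs <- select_pc_count(emb$variance_fractions, pc_target, pc_cap)
  raw <- distance_trajectory(emb, sub$cell_meta$age, table$ladder,
                             n_pcs = n_pcs)
  clamped <- clamp_monotone(raw)
  deltas <- stage_deltas(clamped, table$ladder)
  total <- sum(deltas, na.rm = TRUE)
  cls <- if (total > 0) classify_trajectory(deltas) else NA_integer_
  structure(
    list(cell_type = cell_type, ladder = table$ladder, raw_distance = raw,
         clamped_distance = clamped, stage_deltas = deltas,
         total_change = total, class_label = cls, n_pcs_used = n_pcs,
         n_cells = n_cells(sub)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s': class %s, %d PCs, total change %.3f\n",
              x$cell_type, x$class_label, x$n_pcs_used, x$total_change))
  invisible(x)
}

#' Maturation trajectories for every cell type
#'
#' @inheritParams maturation_trajectory
#' @param cell_types which types to analyse (default all assigned types).
#' @param split_by optional metadata column (e.g. `"sex"`): trajectories
#'   are computed separately per level and returned as a named list of
#'   lists.
#' @param verbose report progress.
#' @return a named list of `trajectory` objects (or list of such lists
#'   when `split_by` is given).
#' @export
maturation_trajectories <- function(table, cell_types = NULL,
                                    split_by = NULL, n_hvg = 2000,
                                    pc_target = 0.20, pc_cap = 100,
                                    verbose = FALSE) {
  if (is.null(cell_types))
    cell_types <- setdiff(sort(unique(table$cell_meta$cell_type)),
                          "unassigned")
  run <- function(mask) {
    out <- lapply(cell_types, function(ctype) {
      if (verbose) message("trajectory: ", ctype)
      maturation_trajectory(table, ctype, n_hvg = n_hvg,
                            pc_target = pc_target, pc_cap = pc_cap,
                            cells = mask)
    })
    names(out) <- cell_types
    out
  }
  if (is.null(split_by)) return(run(NULL))
  levels <- sort(unique(table$cell_meta[[split_by]]))
  out <- lapply(levels, function(lv) run(table$cell_meta[[split_by]] == lv))
  names(out) <- levels
  out
}

#' Tabulate a list of trajectories
#'
#' @param trajs named list of `trajectory` objects.
#' @return long data.frame (cell_type, age, raw, clamped) plus attributes;
#'   see also [trajectory_class_table()].
#' @export
trajectory_table <- function(trajs) {
  do.call(rbind, lapply(trajs, function(tr) {
    data.frame(cell_type = tr$cell_type, age = names(tr$raw_distance),
               raw = unname(tr$raw_distance),
               clamped = unname(tr$clamped_distance),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' @rdname trajectory_table
#' @export
trajectory_class_table <- function(trajs) {
  do.call(rbind, lapply(trajs, function(tr) {
    data.frame(cell_type = tr$cell_type, class_label = tr$class_label,
               n_pcs_used = tr$n_pcs_used, total_change = tr$total_change,
               t(tr$stage_deltas), check.names = FALSE,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Fraction of adult nuclei among each cell's nearest neighbors
#'
#' For every cell, its `k` Euclidean nearest neighbors (self excluded,
#' distance ties broken by cell index) are found among cells of all ages;
#' the per-age maturity value is the number of adult neighbors summed over
#' that age's cells divided by `k` times the number of cells at that age.
#'
#' @param embedding an `embedding` or score matrix.
#' @param ages per-cell age labels.
#' @param ladder an [age_ladder()].
#' @param k neighborhood size, default 50.
#' @return named per-age fraction vector in `[0, 1]`.
#' @export
adult_neighbor_fraction <- function(embedding, ages, ladder, k = 50) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  n <- nrow(scores)
  if (k >= n) stop("validation error: k must be < number of cells")
  ages <- as.character(ages)
  is_adult <- ages == ladder$adult
  sq <- rowSums(scores^2)
  adult_hits <- numeric(n)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = block)) {
    i <- start:min(start + block - 1L, n)
    # squared Euclidean distances of block cells to all cells
    d2 <- outer(sq[i], sq, `+`) - 2 * tcrossprod(scores[i, , drop = FALSE],
                                                 scores)
    for (b in seq_along(i)) {
      row <- d2[b, ]
      row[i[b]] <- Inf  # exclude self
      nb <- order(row, seq_len(n))[seq_len(k)]  # ties by cell index
      adult_hits[i[b]] <- sum(is_adult[nb])
    }
  }
  out <- vapply(ladder$labels, function(a) {
    j <- which(ages == a)
    if (!length(j)) return(NA_real_)
    sum(adult_hits[j]) / (k * length(j))
  }, 0)
  names(out) <- ladder$labels
  out
}

#' Scaled cumulative neighbor-fraction display
#'
#' Cumulative sum of per-age adult-neighbor fractions rescaled to `[0, 1]`,
#' the display convention for comparing maturity timing across cell types.
#'
#' @param fractions per-age fractions from [adult_neighbor_fraction()].
#' @return vector of the same length in `[0, 1]`.
#' @export
scaled_cumulative_fraction <- function(fractions) {
  cs <- cumsum(ifelse(is.na(fractions), 0, fractions))
  rng <- range(cs)
  if (diff(rng) == 0) return(stats::setNames(rep(0, length(cs)),
                                             names(fractions)))
  (cs - rng[1L]) / diff(rng)
}

#' Compare two maturation trajectories (e.g. male vs female)
#'
#' Per-age differences are `b - a` on the clamped distances; the p-value
#' is a two-sided two-sample t-test between the two clamped distance
#' vectors. For cell-type collections, per-age differences are stacked and
#' the t-test pools distances across all cell types.
#'
#' @param traj_a,traj_b `trajectory` objects on the same ladder, or named
#'   lists of them (matched by name).
#' @return list with `difference` (vector or cell-type x age matrix,
#'   convention `b - a`), `p_value`, and `degenerate` flag.
#' @export
compare_trajectories <- function(traj_a, traj_b) {
  if (inherits(traj_a, "trajectory")) {
    traj_a <- list(traj_a)
    traj_b <- list(traj_b)
  } else {
    common <- intersect(names(traj_a), names(traj_b))
    traj_a <- traj_a[common]
    traj_b <- traj_b[common]
  }
  stopifnot(length(traj_a) == length(traj_b), length(traj_a) > 0)
  lab <- traj_a[[1L]]$ladder$labels
  for (i in seq_along(traj_a)) {
    if (!identical(traj_a[[i]]$ladder$labels, traj_b[[i]]$ladder$labels))
      stop("trajectories must share one age ladder")
  }
  av <- do.call(rbind, lapply(traj_a, function(t) t$clamped_distance))
  bv <- do.call(rbind, lapply(traj_b, function(t) t$clamped_distance))
  diffs <- bv - av
  if (length(traj_a) == 1L) diffs <- stats::setNames(drop(diffs), lab)
  x <- stats::na.omit(as.vector(av))
  y <- stats::na.omit(as.vector(bv))
  degenerate <- stats::var(x) + stats::var(y) == 0
  p <- if (degenerate) 1 else stats::t.test(y, x)$p.value
  list(difference = diffs, p_value = p, degenerate = degenerate,
       convention = "b - a")
}
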