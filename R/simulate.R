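#' Cell-type design table for the simulator
#'
#' Builds the `cell_types` argument of [sim_config()]: one row per cell
#' type with its region and maturation class. Stepwise types are assigned a
#' dominant stage cycling over the ladder's stages (mirroring the dominant
#' mid- and late-development steps seen in stepwise cell types).
#'
#' @param n_gradual,n_intermediate,n_stepwise number of cell types per
#'   maturation class.
#' @param regions character vector of region names, recycled over types.
#' @param ladder the [age_ladder()] the step stages live on.
#' @return data.frame with columns `name`, `region`, `class`, `step_stage`.
#' @export
sim_cell_types <- function(n_gradual = 4, n_intermediate = 4,
                           n_stepwise = 4, regions = c("R1", "R2", "R3"),
                           ladder = poa_age_ladder()) {
  cls <- rep(c("gradual", "intermediate", "stepwise"),
             c(n_gradual, n_intermediate, n_stepwise))
  n <- length(cls)
  n_stage <- length(ladder$stage_from)
  step <- rep(NA_integer_, n)
  if (n_stepwise > 0) {
    # stepwise types show dominant mid- and late-development steps
    pool <- unique(c(ceiling((n_stage + 1) / 2), n_stage))
    step[cls == "stepwise"] <- pool[(seq_len(n_stepwise) - 1L) %%
                                      length(pool) + 1L]
  }
  data.frame(
    name = sprintf("CT%02d", seq_len(n)),
    region = rep_len(regions, n),
    class = cls,
    step_stage = step,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' The stated world of the generator: a multi-age, multi-sample,
#' multi-cell-type negative-binomial count dataset with per-cell-type
#' maturation schedules, cell-type markers, region signatures that sharpen
#' with age, sex-effect windows and genotype-dependent developmental
#' delays. Defaults emulate the source study design (8-age ladder, 2
#' samples per sex per age) at desk scale.
#'
#' @param n_genes total number of genes.
#' @param ladder an [age_ladder()].
#' @param cell_types data.frame as returned by [sim_cell_types()].
#' @param samples_per_age_per_sex biological replicates per sex per age
#'   (per genotype).
#' @param cells_per_sample_per_type cells drawn per (sample, cell type).
#' @param n_maturation_genes,n_marker_genes,n_region_genes,n_sex_genes
#'   sizes of the signal gene classes; their sum must not exceed `n_genes`.
#' @param effect_size_log magnitude of every signed log effect, default
#'   `log(4)`.
#' @param sex_effect_windows character vector of stage names from the
#'   ladder's stage set during which sex effects are on; default all
#'   stages (ages covered by a named stage carry the effect).
#' @param sex_affected_celltypes cell-type names carrying sex effects;
#'   `NULL` means all.
#' @param genotype_delays named integer vector: developmental delay in
#'   stages per genotype (the reference genotype should map to 0). Each
#'   delay must be smaller than the number of ages.
#' @param nb_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param libsize_logmean,libsize_logsd log-normal per-cell library factor.
#' @param baseline_logmean,baseline_logsd log-normal per-gene baseline mean.
#' @param seed integer; the single global seed all draws derive from.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 400,
                       ladder = poa_age_ladder(),
                       cell_types = sim_cell_types(ladder = ladder),
                       samples_per_age_per_sex = 2,
                       cells_per_sample_per_type = 50,
                       n_maturation_genes = 200,
                       n_marker_genes = 60,
                       n_region_genes = 60,
                       n_sex_genes = 40,
                       effect_size_log = log(4),
                       sex_effect_windows = ladder$stage_names,
                       sex_affected_celltypes = NULL,
                       genotype_delays = c(WT = 0L),
                       nb_dispersion = 10,
                       libsize_logmean = 0,
                       libsize_logsd = 0.3,
                       baseline_logmean = log(2),
                       baseline_logsd = 1,
                       seed = 1L) {
  stopifnot(inherits(ladder, "age_ladder"),
            is.data.frame(cell_types),
            all(c("name", "region", "class") %in% names(cell_types)),
            samples_per_age_per_sex >= 1,
            cells_per_sample_per_type >= 1,
            nb_dispersion > 0, effect_size_log > 0)
  if (n_maturation_genes + n_marker_genes + n_region_genes + n_sex_genes >
      n_genes)
    stop("signal gene classes exceed n_genes")
  if (is.null(names(genotype_delays)))
    stop("genotype_delays must be named")
  if (any(genotype_delays >= length(ladder$labels)) ||
      any(genotype_delays < 0))
    stop("delays must be in [0, number of ages)")
  bad <- setdiff(sex_effect_windows, ladder$stage_names)
  if (length(bad))
    stop("unknown stage(s) in sex_effect_windows: ",
         paste(bad, collapse = ", "))
  if (is.null(cell_types$step_stage))
    cell_types$step_stage <- NA_integer_
  structure(
    list(n_genes = n_genes, ladder = ladder, cell_types = cell_types,
         samples_per_age_per_sex = samples_per_age_per_sex,
         cells_per_sample_per_type = cells_per_sample_per_type,
         n_maturation_genes = n_maturation_genes,
         n_marker_genes = n_marker_genes,
         n_region_genes = n_region_genes, n_sex_genes = n_sex_genes,
         effect_size_log = effect_size_log,
         sex_effect_windows = sex_effect_windows,
         sex_affected_celltypes = sex_affected_celltypes,
         genotype_delays = genotype_delays,
         nb_dispersion = nb_dispersion,
         libsize_logmean = libsize_logmean, libsize_logsd = libsize_logsd,
         baseline_logmean = baseline_logmean,
         baseline_logsd = baseline_logsd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Maturation schedule over an age ladder
#'
#' Returns the fraction of total maturation m(a) completed at each age:
#' nondecreasing, 0 at the first label, 1 at the adult. `gradual` is linear
#' in the age index; `stepwise` is 0 before its dominant stage and 1 from
#' that stage's later age onward; `intermediate` is a logistic whose change
#' concentrates in the middle three stages.
#'
#' @param shape one of `"gradual"`, `"intermediate"`, `"stepwise"`.
#' @param ladder an [age_ladder()] with at least 3 labels.
#' @param step_stage for `stepwise`: index into the ladder's stage set.
#' @return named numeric vector over the ladder's labels.
#' @export
maturation_schedule <- function(shape, ladder, step_stage = NULL) {
  labs <- ladder$labels
  a <- length(labs)
  if (a < 3) stop("ladder must have at least 3 labels")
  i <- seq_len(a) - 1  # 0-based age index
  m <- switch(
    shape,
    gradual = i / (a - 1),
    stepwise = {
      if (is.null(step_stage) || is.na(step_stage))
        stop("stepwise schedule needs a step_stage")
      n_stage <- length(ladder$stage_from)
      if (step_stage < 1 || step_stage > n_stage)
        stop("step_stage out of range")
      jump_at <- match(ladder$stage_to[step_stage], labs)
      as.numeric(seq_len(a) >= jump_at)
    },
    intermediate = {
      i_first <- match(ladder$stage_from[1L], labs) - 1
      i_last <- match(ladder$stage_to[length(ladder$stage_to)], labs) - 1
      ctr <- (i_first + i_last) / 2
      sc <- (i_last - i_first) / 15
      l <- stats::plogis((i - ctr) / sc)
      (l - l[1L]) / (l[a] - l[1L])
    },
    stop("validation error: unknown schedule shape '", shape, "'")
  )
  names(m) <- labs
  m
}

# ages covered by the configured sex-effect stage windows
sex_window_ages <- function(config) {
  k <- match(config$sex_effect_windows, config$ladder$stage_names)
  unique(c(config$ladder$stage_from[k], config$ladder$stage_to[k]))
}

# builds the ground-truth gene/effect bookkeeping (no RNG beyond caller's)
build_sim_truth <- function(config) {
  lad <- config$ladder
  ct <- config$cell_types
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  baseline_log <- stats::rnorm(config$n_genes, config$baseline_logmean,
                               config$baseline_logsd)

  idx <- 0L
  take <- function(n) {
    out <- if (n > 0) (idx + 1L):(idx + n) else integer(0)
    idx <<- idx + n
    out
  }
  signed <- function(n) config$effect_size_log * rep_len(c(1, -1), n)

  mat_i <- take(config$n_maturation_genes)
  maturation_genes <- data.frame(gene_id = gene_ids[mat_i],
                                 effect = signed(length(mat_i)),
                                 stringsAsFactors = FALSE)
  mark_i <- take(config$n_marker_genes)
  marker_genes <- data.frame(gene_id = gene_ids[mark_i],
                             cell_type = rep_len(ct$name, length(mark_i)),
                             effect = rep(config$effect_size_log,
                                          length(mark_i)),
                             stringsAsFactors = FALSE)
  reg_i <- take(config$n_region_genes)
  region_genes <- data.frame(gene_id = gene_ids[reg_i],
                             region = rep_len(unique(ct$region),
                                              length(reg_i)),
                             effect = rep(config$effect_size_log,
                                          length(reg_i)),
                             stringsAsFactors = FALSE)
  sex_i <- take(config$n_sex_genes)
  sex_genes <- data.frame(gene_id = gene_ids[sex_i],
                          effect = signed(length(sex_i)),
                          stringsAsFactors = FALSE)

  schedule <- t(vapply(seq_len(nrow(ct)), function(r) {
    maturation_schedule(ct$class[r], lad, ct$step_stage[r])
  }, numeric(length(lad$labels))))
  dimnames(schedule) <- list(ct$name, lad$labels)

  true_class <- apply(schedule, 1L, function(m) {
    d <- schedule_stage_deltas(m, lad)
    classify_trajectory(d)
  })

  structure(
    list(gene_ids = gene_ids, baseline_log = baseline_log,
         schedule = schedule, true_class = true_class,
         maturation_genes = maturation_genes, marker_genes = marker_genes,
         region_genes = region_genes, sex_genes = sex_genes,
         sex_affected_celltypes = config$sex_affected_celltypes %||%
           ct$name,
         sex_window_ages = sex_window_ages(config),
         delay = config$genotype_delays),
    class = "sim_truth"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stage deltas of a noiseless schedule: maturation accrued per stage
schedule_stage_deltas <- function(m, ladder) {
  m[match(ladder$stage_to, ladder$labels)] -
    m[match(ladder$stage_from, ladder$labels)]
}

# per-gene log-mean for one (cell type, age, sex, genotype) condition
condition_log_mean <- function(truth, config, cell_type, age, sex,
                               genotype) {
  lad <- config$ladder
  ct <- config$cell_types
  r <- match(cell_type, ct$name)
  if (is.na(r)) stop("unknown cell type: ", cell_type)
  a_idx <- age_index(lad, age)
  n_ages <- length(lad$labels)

  lm <- truth$baseline_log

  mi <- match(truth$marker_genes$gene_id[
    truth$marker_genes$cell_type == cell_type], truth$gene_ids)
  if (length(mi))
    lm[mi] <- lm[mi] + truth$marker_genes$effect[
      truth$marker_genes$cell_type == cell_type]

  r_age <- 0.25 + 0.75 * (a_idx - 1) / (n_ages - 1)  # region sharpening
  own_reg <- truth$region_genes$region == ct$region[r]
  ri <- match(truth$region_genes$gene_id[own_reg], truth$gene_ids)
  if (length(ri))
    lm[ri] <- lm[ri] + truth$region_genes$effect[own_reg] * r_age

  delay <- truth$delay[[genotype]]
  if (is.null(delay)) stop("unknown genotype: ", genotype)
  a_eff <- max(1L, a_idx - as.integer(delay))  # schedule look-back, clamped
  m_val <- truth$schedule[cell_type, a_eff]
  gi <- match(truth$maturation_genes$gene_id, truth$gene_ids)
  lm[gi] <- lm[gi] + truth$maturation_genes$effect * m_val

  if (sex == "M" && lad$labels[a_idx] %in% truth$sex_window_ages &&
      cell_type %in% truth$sex_affected_celltypes) {
    si <- match(truth$sex_genes$gene_id, truth$gene_ids)
    lm[si] <- lm[si] + truth$sex_genes$effect
  }
  lm
}

#' Expected mean count for one gene in one condition
#'
#' The noiseless negative-binomial mean (before the per-cell library
#' factor): `exp(log baseline + marker + region * r(age) + maturation *
#' m(age') + sex-window effect)`, where `age'` is the age shifted back by
#' the genotype's delay (clamped at the first label) and the region effect
#' sharpens linearly from 0.25 to 1 across ages.
#'
#' @param gene gene id.
#' @param cell_type cell-type name.
#' @param age age label.
#' @param sex `"F"` or `"M"`.
#' @param genotype genotype name known to the truth's delay table.
#' @param truth a `sim_truth`.
#' @param config the [sim_config()] that produced it.
#' @return positive scalar mean.
#' @export
expected_mean <- function(gene, cell_type, age, sex, genotype, truth,
                          config) {
  g <- match(gene, truth$gene_ids)
  if (is.na(g)) stop("unknown gene: ", gene)
  lm <- condition_log_mean(truth, config, cell_type, age, sex, genotype)
  exp(lm[g])
}

#' Simulate a developmental single-nucleus count dataset
#'
#' Draws negative-binomial counts with mean `expected_mean x` a log-normal
#' per-cell library factor and dispersion `nb_dispersion`, over the full
#' sample grid genotype x age x sex x replicate, with
#' `cells_per_sample_per_type` cells per cell type in every sample.
#' Identical `(config, seed)` give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `table` (a [cell_table()]) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  truth <- build_sim_truth(config)
  lad <- config$ladder
  ct <- config$cell_types
  genos <- names(config$genotype_delays)
  ncpb <- config$cells_per_sample_per_type

  grid <- expand.grid(rep = seq_len(config$samples_per_age_per_sex),
                      sex = c("F", "M"), age = lad$labels,
                      genotype = genos, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_%s_r%d", grid$genotype, grid$age,
                            grid$sex, grid$rep)

  blocks <- vector("list", nrow(grid) * nrow(ct))
  meta <- vector("list", length(blocks))
  b <- 0L
  cell_n <- 0L
  for (s in seq_len(nrow(grid))) {
    for (r in seq_len(nrow(ct))) {
      lm <- condition_log_mean(truth, config, ct$name[r], grid$age[s],
                               grid$sex[s], grid$genotype[s])
      libf <- exp(stats::rnorm(ncpb, config$libsize_logmean,
                               config$libsize_logsd))
      mu <- exp(lm) %o% libf
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = config$nb_dispersion),
                    nrow = config$n_genes)
      b <- b + 1L
      blocks[[b]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                 "generalMatrix")
      meta[[b]] <- data.frame(
        cell_id = sprintf("c%06d", cell_n + seq_len(ncpb)),
        sample_id = grid$sample_id[s], age = grid$age[s],
        sex = grid$sex[s], genotype = grid$genotype[s],
        cell_type = ct$name[r], region = ct$region[r],
        stringsAsFactors = FALSE)
      cell_n <- cell_n + ncpb
    }
  }
  counts <- do.call(cbind, blocks)
  cell_meta <- do.call(rbind, meta)
  table <- cell_table(counts, truth$gene_ids, cell_meta, lad)
  list(table = table, truth = truth)
}

#' Write generator ground truth as TSV tables
#'
#' @param truth a `sim_truth` from [simulate_dataset()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_sim_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  sched <- data.frame(cell_type = rownames(truth$schedule),
                      truth$schedule, check.names = FALSE)
  paths <- c(
    w(sched, "truth_schedule.tsv"),
    w(data.frame(cell_type = names(truth$true_class),
                 true_class = truth$true_class), "truth_class.tsv"),
    w(truth$maturation_genes, "truth_maturation_genes.tsv"),
    w(truth$marker_genes, "truth_marker_genes.tsv"),
    w(truth$region_genes, "truth_region_genes.tsv"),
    w(truth$sex_genes, "truth_sex_genes.tsv"),
    w(data.frame(genotype = names(truth$delay),
                 delay_stages = as.integer(truth$delay)),
      "truth_delay.tsv"))
  invisible(paths)
}
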