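#' Run the full developmental-trajectory pipeline on simulated data
#'
#' Simulates a dataset from `config` (with the seed overridden by `seed`),
#' applies QC, and runs every analysis stage: maturation trajectories and
#' classes, sex contrasts, devDEGs with sharing classification,
#' within-region correlation trends, identity mapping of the youngest age
#' onto the adult, and (when the config carries a delayed genotype) the
#' pseudotime delay test. All result tables are written as TSV under
#' `out_dir`; outputs are bit-identical across runs with the same
#' `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding `config$seed`.
#' @param qc a [qc_params()] suited to the simulated scale; the default is
#'   permissive so the simulated library sizes are not truncated.
#' @return invisibly, a named list of the result data structures.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         qc = qc_params(min_umi = 10, max_umi = 1e6,
                                        min_genes = 5,
                                        max_top_gene_frac = 0.5)) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)

  sim <- simulate_dataset(config)
  write_sim_truth(sim$truth, out_dir)
  table <- qc_filter(sim$table, qc, verbose = FALSE)
  lad <- table$ladder

  # maturation trajectories
  trajs <- maturation_trajectories(table)
  w(trajectory_table(trajs), "trajectories.tsv")
  w(trajectory_class_table(trajs), "trajectory_classes.tsv")

  # sex contrast across cell types
  contrast <- contrast_all_celltypes(table, "sex")
  w(contrast, "sex_contrast.tsv")

  # devDEGs per cell type + sharing
  cts <- sort(unique(table$cell_meta$cell_type))
  devs <- lapply(cts, function(ctype) dev_de(table, ctype))
  names(devs) <- cts
  sets <- lapply(devs, function(d) d$gene_id[d$significant])
  sharing <- classify_sharing(sets)
  w(sharing, "devdeg_sharing.tsv")
  w(data.frame(cell_type = cts,
               n_devdeg = vapply(sets, length, 0L)), "devdeg_counts.tsv")

  # regionalization trend
  regions <- vapply(split(table$cell_meta$region,
                          table$cell_meta$cell_type), `[`, "", 1L)
  corr_by_age <- celltype_correlation_by_age(table)
  region_trend <- within_region_correlation(corr_by_age, regions,
                                            lad$adult)
  w(region_trend, "region_trend.tsv")

  # identity mapping: youngest age onto adult reference
  adult <- subset_cells(table, table$cell_meta$age == lad$adult)
  young <- subset_cells(table, table$cell_meta$age == lad$labels[1L])
  ref_scaled <- scale_genes(lognormalize(adult))
  ref_prof <- celltype_profiles(ref_scaled, adult$cell_meta$cell_type)
  scores <- soft_classify(scale_genes(lognormalize(young)), ref_prof)
  pm <- prediction_matrix(scores, young$cell_meta$cell_type)
  ir <- identity_ratios(pm)
  w(data.frame(cell_type = names(ir), identity_ratio = unname(ir)),
    "identity_ratio.tsv")

  delay <- NULL
  genos <- names(config$genotype_delays)
  if (length(genos) >= 2L) {
    ref_g <- genos[which.min(config$genotype_delays)]
    mut_g <- genos[which.max(config$genotype_delays)]
    mid_age <- lad$labels[ceiling(length(lad$labels) / 2)]
    delay <- pseudotime_delay(table, cts[1L], ref_g, mut_g,
                              ages = mid_age)
    w(delay$pseudotime, "pseudotime.tsv")
    w(delay$test$sample_means, "pseudotime_sample_means.tsv")
    gm <- delay$test$group_means
    w(data.frame(control = ref_g, mutant = mut_g,
                 difference = gm[[mut_g]] - gm[[ref_g]],
                 p_value = delay$test$p_value), "pseudotime_test.tsv")
  }

  manifest <- list(seed = config$seed, n_genes = config$n_genes,
                   ages = lad$labels,
                   n_cell_types = nrow(config$cell_types),
                   samples_per_age_per_sex =
                     config$samples_per_age_per_sex,
                   cells_per_sample_per_type =
                     config$cells_per_sample_per_type,
                   genotypes = as.list(config$genotype_delays))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(table = table, truth = sim$truth, trajectories = trajs,
                 contrast = contrast, devdegs = devs, sharing = sharing,
                 region_trend = region_trend, identity_ratios = ir,
                 delay = delay))
}
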