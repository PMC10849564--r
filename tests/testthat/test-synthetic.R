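test_that("maturation schedules match their shape definitions", {
  lad <- lad6()
  expect_equal(unname(maturation_schedule("gradual", lad)),
               c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(unname(maturation_schedule("stepwise", lad,
                                          step_stage = 4)),
               c(0, 0, 0, 0, 1, 1))
  # every shape: nondecreasing, endpoints 0 and 1
  shapes <- list(c("gradual", NA), c("intermediate", NA),
                 c("stepwise", 1), c("stepwise", 3), c("stepwise", 5))
  for (ladder in list(lad, poa_age_ladder(),
                      age_ladder(c("A", "B", "C", "D")))) {
    for (sh in shapes) {
      st <- suppressWarnings(as.integer(sh[2]))
      if (!is.na(st) && st > length(ladder$stage_from)) next
      m <- maturation_schedule(sh[1], ladder, step_stage = st)
      expect_true(all(diff(m) >= 0))
      expect_equal(unname(m[1]), 0)
      expect_equal(unname(m[length(m)]), 1)
    }
  }
  expect_error(maturation_schedule("bogus", lad), "validation error")
})

test_that("expected_mean composes baseline, maturation, sex and delay", {
  lad <- lad6()
  ct <- sim_cell_types(1, 0, 0, ladder = lad)
  base_cfg <- function(...) sim_config(
    ladder = lad, cell_types = ct, n_genes = 20,
    n_marker_genes = 0, n_region_genes = 0, effect_size_log = log(2),
    genotype_delays = c(WT = 0L, MUT = 1L), seed = 9, ...)
  # all effects zero -> baseline
  cfg0 <- base_cfg(n_maturation_genes = 0, n_sex_genes = 0)
  truth0 <- simulate_dataset(cfg0)$truth
  g <- truth0$gene_ids[5]
  expect_equal(expected_mean(g, "CT01", "P0", "F", "WT", truth0, cfg0),
               exp(truth0$baseline_log[5]))
  # maturation gene with effect log 2 at m = 1 -> baseline x 2
  cfg1 <- base_cfg(n_maturation_genes = 2, n_sex_genes = 0)
  truth1 <- simulate_dataset(cfg1)$truth
  g1 <- truth1$maturation_genes$gene_id[1]  # signed +log(2)
  expect_equal(
    expected_mean(g1, "CT01", "P65", "F", "WT", truth1, cfg1),
    exp(truth1$baseline_log[1]) * 2)
  # delayed genotype at P10 uses the schedule value at P4
  expect_equal(
    expected_mean(g1, "CT01", "P10", "F", "MUT", truth1, cfg1),
    expected_mean(g1, "CT01", "P4", "F", "WT", truth1, cfg1))
  # sex gene active for males inside the window only
  cfg2 <- base_cfg(n_maturation_genes = 0, n_sex_genes = 1,
                   sex_effect_windows = "P4-P10")
  truth2 <- simulate_dataset(cfg2)$truth
  gs <- truth2$sex_genes$gene_id[1]
  f_val <- expected_mean(gs, "CT01", "P10", "F", "WT", truth2, cfg2)
  expect_equal(
    expected_mean(gs, "CT01", "P10", "M", "WT", truth2, cfg2), 2 * f_val)
  expect_equal(
    expected_mean(gs, "CT01", "P65", "M", "WT", truth2, cfg2),
    expected_mean(gs, "CT01", "P65", "F", "WT", truth2, cfg2))
})

test_that("simulate_dataset is seeded, calibrated and overdispersed", {
  lad3 <- age_ladder(c("P0", "P10", "P65"))
  ct <- sim_cell_types(1, 0, 0, ladder = lad3)
  cfg <- sim_config(ladder = lad3, cell_types = ct, n_genes = 20,
                    n_maturation_genes = 0, n_marker_genes = 0,
                    n_region_genes = 0, n_sex_genes = 0,
                    cells_per_sample_per_type = 2500,
                    libsize_logsd = 0, seed = 21)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(sim1$table$counts),
                   as.matrix(sim2$table$counts))  # bit-identical
  # Monte-Carlo: 10,000 draws of one condition within 3 SE of the mean
  meta <- sim1$table$cell_meta
  idx <- which(meta$age == "P0" & meta$sex == "F")
  expect_gte(length(idx), 5000)
  cfgv <- cfg
  for (g in c(1L, 11L)) {
    draws <- as.numeric(sim1$table$counts[g, idx])
    mu <- expected_mean(sim1$truth$gene_ids[g], "CT01", "P0", "F", "WT",
                        sim1$truth, cfg)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - mu), 3 * se)
    # overdispersion: empirical variance exceeds the mean
    expect_gt(var(draws), mean(draws))
  }
})

test_that("ground truth bookkeeping matches the configuration", {
  lad <- lad6()
  ct <- sim_cell_types(2, 2, 2, ladder = lad)
  cfg <- sim_config(ladder = lad, cell_types = ct, n_genes = 100,
                    n_maturation_genes = 30, n_marker_genes = 12,
                    n_region_genes = 9, n_sex_genes = 7,
                    cells_per_sample_per_type = 2, seed = 2)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr$maturation_genes), 30)
  expect_equal(nrow(tr$marker_genes), 12)
  expect_equal(nrow(tr$region_genes), 9)
  expect_equal(nrow(tr$sex_genes), 7)
  # gene classes are disjoint
  all_ids <- c(tr$maturation_genes$gene_id, tr$marker_genes$gene_id,
               tr$region_genes$gene_id, tr$sex_genes$gene_id)
  expect_false(anyDuplicated(all_ids) > 0)
  # metadata grid: every (sample, cell type) block has the right size
  tab <- table(sim$table$cell_meta$sample_id,
               sim$table$cell_meta$cell_type)
  expect_true(all(tab == 2))
  expect_equal(nrow(tab), 2 * 2 * 6)  # sex x replicate x age
})

test_that("true_class agrees with the classifier on noiseless distances", {
  for (lad in list(lad6(), poa_age_ladder())) {
    n_stage <- length(lad$stage_from)
    ct <- sim_cell_types(2, 2, n_stage, ladder = lad)
    ct$step_stage[ct$class == "stepwise"] <- seq_len(n_stage)
    cfg <- sim_config(ladder = lad, cell_types = ct, n_genes = 10,
                      n_maturation_genes = 0, n_marker_genes = 0,
                      n_region_genes = 0, n_sex_genes = 0,
                      cells_per_sample_per_type = 1, seed = 3)
    truth <- simulate_dataset(cfg)$truth
    for (nm in rownames(truth$schedule)) {
      d <- 7 * (1 - truth$schedule[nm, ])        # distances from schedule
      deltas <- stage_deltas(clamp_monotone(d), lad)
      expect_identical(classify_trajectory(deltas),
                       truth$true_class[[nm]])
    }
  }
})

test_that("truth tables are written as TSV", {
  lad <- lad6()
  cfg <- sim_config(ladder = lad,
                    cell_types = sim_cell_types(1, 1, 1, ladder = lad),
                    n_genes = 50, n_maturation_genes = 10,
                    n_marker_genes = 6, n_region_genes = 6,
                    n_sex_genes = 4, cells_per_sample_per_type = 1,
                    seed = 4)
  truth <- simulate_dataset(cfg)$truth
  dir <- withr::local_tempdir()
  write_sim_truth(truth, dir)
  cls <- read.delim(file.path(dir, "truth_class.tsv"))
  expect_equal(cls$true_class,
               unname(truth$true_class[cls$cell_type]))
  sched <- read.delim(file.path(dir, "truth_schedule.tsv"),
                      check.names = FALSE)
  expect_equal(as.matrix(sched[, -1]), truth$schedule,
               ignore_attr = TRUE)
})
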