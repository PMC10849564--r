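test_that("dev_de recovers maturation genes and spares baseline genes", {
  lad <- lad6()
  ct <- sim_cell_types(1, 0, 0, ladder = lad)
  cfg <- sim_config(ladder = lad, cell_types = ct, n_genes = 300,
                    n_maturation_genes = 100, n_marker_genes = 0,
                    n_region_genes = 0, n_sex_genes = 0,
                    cells_per_sample_per_type = 15, seed = 12)
  sim <- simulate_dataset(cfg)
  de <- dev_de(sim$table, "CT01")
  mat <- sim$truth$maturation_genes$gene_id
  hit <- mean(de$significant[match(mat, de$gene_id)])
  expect_gt(hit, 0.9)
  # baseline genes are called far less often; they are not fully null in
  # CPM space because the maturation ramp shifts library composition
  null_hit <- mean(de$significant[!(de$gene_id %in% mat)])
  expect_lt(null_hit, hit / 2)
  expect_error(dev_de(sim$table, "CT01", ages = "P65"), ">= 2 ages")
})

test_that("classify_sharing applies strict 70%/20% cutoffs", {
  sets <- c(lapply(1:8, function(i) c("shared_g", "mid_g")),
            lapply(9:10, function(i) character(0)))
  names(sets) <- paste0("ct", 1:10)
  sets$ct1 <- c(sets$ct1, "rare_g")
  sets$ct9 <- "mid_g"  # mid_g in 9 of 10? no: keep at 7 below
  sets <- lapply(sets, unique)
  # shared_g in 8/10 (>70%), rare_g in 1/10 (<20%)
  out <- classify_sharing(sets)
  expect_equal(out$label[out$gene_id == "shared_g"], "shared")
  expect_equal(out$label[out$gene_id == "rare_g"], "specific")
  # exactly 7 of 10 (f = 0.7) is intermediate under strict inequality
  sets7 <- c(lapply(1:7, function(i) "edge_g"),
             lapply(8:10, function(i) character(0)))
  names(sets7) <- paste0("ct", 1:10)
  out7 <- classify_sharing(sets7)
  expect_equal(out7$label, "intermediate")
  # exhaustive and exclusive partition
  expect_true(all(out$label %in% c("shared", "intermediate", "specific")))
  expect_equal(nrow(out), length(unique(unlist(sets))))
})

test_that("fit_trend reproduces constants and straight lines", {
  lad <- lad6()
  ages <- rep(lad$labels, each = 3)
  const <- fit_trend(rep(2.5, length(ages)), ages, lad)
  expect_equal(unname(const), rep(2.5, 6))
  lin <- 0.7 * age_index(lad, ages) + 1
  tr <- fit_trend(lin, ages, lad)
  expect_equal(unname(tr), 0.7 * (1:6) + 1, tolerance = 1e-6)
  expect_error(fit_trend(1:6, rep(c("P0", "P65"), 3), lad),
               "validation error")
})

test_that("fit_trend recovers a noisy step within 10% at the ends", {
  lad <- lad6()
  set.seed(31)
  ages <- rep(lad$labels, each = 8)
  truth <- ifelse(age_index(lad, ages) >= 4, 10, 5)
  y <- truth + rnorm(length(ages), sd = 0.4)
  tr <- fit_trend(y, ages, lad)
  expect_lt(abs(tr[["P0"]] - 5) / 5, 0.1)
  expect_lt(abs(tr[["P65"]] - 10) / 10, 0.1)
})

test_that("cluster_trends recovers planted shapes deterministically", {
  set.seed(9)
  rising <- t(replicate(25, seq(0, 1, length.out = 6) +
                          rnorm(6, sd = 0.05)))
  falling <- t(replicate(25, seq(1, 0, length.out = 6) +
                           rnorm(6, sd = 0.05)))
  trends <- rbind(rising, falling)
  cl <- cluster_trends(trends, 2)
  expect_equal(ari(cl, rep(1:2, each = 25)), 1)
  # permuting input order yields the identical partition
  perm <- sample(nrow(trends))
  cl_perm <- cluster_trends(trends[perm, ], 2)
  expect_equal(ari(cl_perm, cl[perm]), 1)
  # identical trends are co-assigned
  same <- matrix(rep(1:6, each = 5), nrow = 5, byrow = FALSE)
  expect_equal(length(unique(cluster_trends(same + 0, 2))), 2)
  expect_error(cluster_trends(trends[1:3, ], 5), "n_clusters")
})

test_that("module_score is seeded and detects enriched sets", {
  set.seed(14)
  m <- matrix(rexp(2000 * 80), nrow = 2000,
              dimnames = list(sprintf("g%04d", 1:2000), NULL))
  # a set drawn like its control pool scores near zero on average
  rand_set <- sample(rownames(m), 20)
  s0 <- module_score(m, rand_set, seed = 3)
  expect_lt(abs(mean(s0)), 0.15)
  expect_identical(module_score(m, rand_set, seed = 3), s0)  # seeded
  expect_false(identical(module_score(m, rand_set, seed = 4), s0))
  # uniformly doubled set genes score positive in nearly all cells
  m2 <- m
  m2[rand_set, ] <- m2[rand_set, ] + 2
  s2 <- module_score(m2, rand_set, seed = 3)
  expect_gt(mean(s2 > 0), 0.99)
  expect_error(module_score(m, c("absent1", "absent2"), seed = 1),
               "validation error")
})

test_that("aggregate_score_by_age z-scores per-age means", {
  scores <- c(1, 1, 2, 2, 6, 6)
  ages <- rep(c("P0", "P10", "P65"), each = 2)
  z <- aggregate_score_by_age(scores, ages,
                              ladder = age_ladder(c("P0", "P10", "P65")))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_true(all(diff(z) > 0))  # monotone means stay monotone
  expect_equal(unname(aggregate_score_by_age(rep(3, 4),
                                             rep(c("P0", "P65"), 2))),
               c(0, 0))
  expect_error(aggregate_score_by_age(1:3, rep("P0", 3)),
               "validation error")
})

test_that("refinement_score follows the combination-count arithmetic", {
  genes <- paste0("g", 1:10)
  cts <- paste0("ct", 1:5)
  # all 10 genes expressed everywhere except 2 combos
  expressed <- setNames(rep(list(genes), 5), cts)
  expressed$ct1 <- setdiff(genes, "g1")
  expressed$ct2 <- setdiff(genes, "g2")
  mk_de <- function(sig) {
    data.frame(gene_id = genes, significant = genes %in% sig,
               stringsAsFactors = FALSE)
  }
  devs <- setNames(list(mk_de("g3"), mk_de("g4"), mk_de("g5"),
                        mk_de(character(0)), mk_de(character(0))), cts)
  rs <- refinement_score(devs, genes, expressed)
  expect_equal(rs$score, 3 / 48)
  expect_equal(rs$n_expressed, 48)
  # never-expressed gene added to the set leaves the score unchanged
  rs2 <- refinement_score(devs, c(genes, "ghost"), expressed)
  expect_equal(rs2$score, rs$score)
  # bounds
  none <- setNames(rep(list(mk_de(character(0))), 5), cts)
  expect_equal(refinement_score(none, genes, expressed)$score, 0)
  all_sig <- setNames(rep(list(mk_de(genes)), 5), cts)
  expect_equal(refinement_score(all_sig, genes, expressed)$score, 1)
})

test_that("refinement_score_for_set works end to end on generator data", {
  lad <- lad6()
  ct <- sim_cell_types(2, 0, 0, ladder = lad)
  cfg <- sim_config(ladder = lad, cell_types = ct, n_genes = 200,
                    n_maturation_genes = 80, n_marker_genes = 0,
                    n_region_genes = 0, n_sex_genes = 0,
                    cells_per_sample_per_type = 12, seed = 13)
  sim <- simulate_dataset(cfg)
  mat_set <- sim$truth$maturation_genes$gene_id
  base_set <- setdiff(sim$truth$gene_ids, mat_set)[1:40]
  rs_mat <- refinement_score_for_set(sim$table, mat_set,
                                     young_age = "P10")
  rs_base <- refinement_score_for_set(sim$table, base_set,
                                      young_age = "P10")
  expect_gte(rs_mat$score, 0); expect_lte(rs_mat$score, 1)
  expect_gt(rs_mat$score, rs_base$score)
  expect_gt(rs_mat$score, 0.5)   # P10 -> P65 completes ~40% of a 4x ramp
  expect_lt(rs_base$score, 0.2)
})

test_that("gene-set catalogs read from TSV and resolve against a universe", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.tsv")
  write.table(data.frame(set_name = c("a", "a", "b"),
                         gene_id = c("g1", "gX", "g2")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- suppressMessages(read_gene_sets(path,
                                          universe = c("g1", "g2")))
  expect_equal(sets, list(a = "g1", b = "g2"))
})
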