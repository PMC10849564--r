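test_that("select_pc_count implements the 20%-variance rule with cap", {
  expect_equal(select_pc_count(c(0.5, 0.3, 0.2), target = 0.2), 1L)
  expect_equal(select_pc_count(rep(0.0005, 1000), target = 0.2,
                               cap = 100), 100L)
  expect_equal(select_pc_count(c(0.10, 0.06, 0.05), target = 0.2), 3L)
  # target never reached and fewer components than the cap
  expect_equal(select_pc_count(c(0.05, 0.04), target = 0.2, cap = 100), 2L)
  expect_error(select_pc_count(numeric(0)), "validation error")
})

test_that("distance_trajectory takes Manhattan centroid distances", {
  lad <- age_ladder(c("P0", "P10", "P65"))
  scores <- rbind(c(0, 0), c(0, 0),    # P0 centroid (0,0)
                  c(1, 7),             # single P10 cell
                  c(3, 4), c(3, 4))    # adult centroid (3,4)
  d <- distance_trajectory(scores, c("P0", "P0", "P10", "P65", "P65"),
                           lad)
  expect_equal(unname(d), c(7, abs(1 - 3) + abs(7 - 4), 0))
  # an age with no cells is NA-flagged
  d2 <- distance_trajectory(scores[-3, , drop = FALSE],
                            c("P0", "P0", "P65", "P65"), lad)
  expect_true(is.na(d2[["P10"]]))
  expect_error(distance_trajectory(scores, rep("P0", 5), lad), "adult")
})

test_that("clamp_monotone replaces increases with the previous value", {
  expect_equal(clamp_monotone(c(10, 8, 9, 5, 0)), c(10, 8, 8, 5, 0))
  expect_equal(clamp_monotone(c(9, 7, 5, 2, 0)), c(9, 7, 5, 2, 0))
  expect_equal(clamp_monotone(c(5, 6, 7)), c(5, 5, 5))
  # property: never increases any value, output nonincreasing
  set.seed(3)
  for (i in 1:20) {
    x <- runif(8, 0, 10)
    cl <- clamp_monotone(x)
    expect_true(all(cl <= x))
    expect_true(all(diff(cl) <= 0))
  }
})

test_that("classify_trajectory implements the 90% stage-count rule", {
  expect_equal(classify_trajectory(c(0.95, 0.05, 0, 0, 0)), 3L)
  expect_equal(classify_trajectory(rep(0.2, 5)), 1L)
  expect_equal(classify_trajectory(c(0.4, 0.3, 0.2, 0.05, 0.05)), 2L)
  # boundary: exactly 90% in two stages is still stepwise
  expect_equal(classify_trajectory(c(0.45, 0.45, 0.1, 0, 0)), 3L)
  expect_warning(cls <- classify_trajectory(rep(0, 5)), "undefined")
  expect_true(is.na(cls))
  # generalization away from 5 stages keeps the fractional cutpoints
  expect_equal(classify_trajectory(c(1, 0, 0, 0)), 3L)       # 1/4 <= 0.4
  expect_equal(classify_trajectory(rep(0.25, 4)), 1L)        # 4/4 > 0.6
})

test_that("stage deltas on the clamped curve sum to the total change", {
  lad <- lad6()
  raw <- c(P0 = 10, P4 = 8, P10 = 9, P18 = 4, P28 = 2, P65 = 0)
  cl <- clamp_monotone(raw)
  d <- stage_deltas(cl, lad)
  expect_true(all(d >= 0))
  expect_equal(sum(d), cl[["P0"]] - cl[["P65"]])
  expect_named(d, lad$stage_names)
})

test_that("adult_neighbor_fraction matches brute-force kNN enumeration", {
  lad2 <- age_ladder(c("P0", "P65"))
  # 1-D toy: young cluster far from adult cluster
  emb <- cbind(c(0, 0.1, 0.2, 10, 10.1, 10.2))
  ages <- c("P0", "P0", "P0", "P65", "P65", "P65")
  fr <- adult_neighbor_fraction(emb, ages, lad2, k = 2)
  expect_equal(unname(fr), c(0, 1))
  # random data: brute-force oracle with index tie-breaks
  set.seed(11)
  x <- matrix(rnorm(40 * 3), nrow = 40)
  ages2 <- rep(c("P0", "P65"), each = 20)
  k <- 5
  fr2 <- adult_neighbor_fraction(x, ages2, lad2, k = k)
  hits <- sapply(seq_len(40), function(i) {
    d <- colSums((t(x) - x[i, ])^2)
    d[i] <- Inf
    nb <- order(d, seq_len(40))[1:k]
    sum(ages2[nb] == "P65")
  })
  expect_equal(unname(fr2),
               c(sum(hits[1:20]) / (k * 20), sum(hits[21:40]) / (k * 20)))
  expect_true(all(fr2 >= 0 & fr2 <= 1))
  expect_error(adult_neighbor_fraction(emb, ages, lad2, k = 6),
               "validation error")
})

test_that("scaled cumulative neighbor fractions span [0, 1]", {
  fr <- c(P0 = 0.1, P10 = 0.3, P65 = 0.6)
  sc <- scaled_cumulative_fraction(fr)
  expect_equal(unname(sc[1]), 0)
  expect_equal(unname(sc[3]), 1)
  expect_true(all(diff(sc) >= 0))
})

test_that("compare_trajectories reports b - a differences and a t-test", {
  lad <- lad6()
  mk_traj <- function(cl) {
    structure(list(cell_type = "T", ladder = lad,
                   raw_distance = cl, clamped_distance = cl,
                   stage_deltas = stage_deltas(cl, lad),
                   total_change = cl[[1]], class_label = 1L,
                   n_pcs_used = 2L, n_cells = 10L),
              class = "trajectory")
  }
  a <- mk_traj(c(P0 = 8, P4 = 7, P10 = 5, P18 = 3, P28 = 1, P65 = 0))
  b <- mk_traj(c(P0 = 9, P4 = 8, P10 = 6, P18 = 4, P28 = 2, P65 = 1))
  same <- compare_trajectories(a, a)
  expect_true(all(same$difference == 0))
  shifted <- compare_trajectories(a, b)
  expect_true(all(shifted$difference == 1))
  # p-value equals the textbook Welch formula on the same vectors
  expect_equal(shifted$p_value,
               welch_p(a$clamped_distance, b$clamped_distance))
  flat <- mk_traj(c(P0 = 0, P4 = 0, P10 = 0, P18 = 0, P28 = 0, P65 = 0))
  deg <- compare_trajectories(flat, flat)
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("per-cell-type pipeline yields clamped, classed trajectories", {
  lad <- lad6()
  cfg <- sim_config(ladder = lad,
                    cell_types = sim_cell_types(1, 0, 1, ladder = lad),
                    n_genes = 200, n_maturation_genes = 100,
                    n_marker_genes = 20, n_region_genes = 20,
                    n_sex_genes = 10, cells_per_sample_per_type = 15,
                    seed = 5)
  sim <- simulate_dataset(cfg)
  trajs <- maturation_trajectories(sim$table)
  for (tr in trajs) {
    expect_true(all(diff(tr$clamped_distance) <= 0))
    expect_equal(unname(tr$clamped_distance[["P65"]]), 0)
    expect_true(all(tr$clamped_distance <= tr$raw_distance))
    expect_equal(sum(tr$stage_deltas), tr$total_change)
    expect_gte(tr$n_pcs_used, 1L)
  }
  # split-by-sex mode returns one trajectory set per level
  split <- maturation_trajectories(sim$table, split_by = "sex")
  expect_named(split, c("F", "M"))
  expect_named(split$F, names(trajs))
})
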