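test_that("cell table round-trips through Matrix Market + TSV exactly", {
  lad <- lad6()
  set.seed(42)
  counts <- matrix(rpois(60, 2), nrow = 10)
  meta <- make_meta(6, ages = c("P0", "P0", "P10", "P10", "P65", "P65"),
                    sample_id = rep(c("a", "b"), 3))
  tab <- cell_table(counts, paste0("g", 1:10), meta, lad)
  dir <- withr::local_tempdir()
  write_cell_table(tab, dir)
  back <- read_cell_table(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "cells.tsv"), lad)
  expect_equal(as.matrix(back$counts), as.matrix(tab$counts))
  expect_identical(back$gene_ids, tab$gene_ids)
  expect_identical(back$cell_meta, tab$cell_meta)
})

test_that("malformed inputs are rejected as format errors", {
  lad <- lad6()
  counts <- matrix(1, nrow = 3, ncol = 2)
  meta <- make_meta(2, ages = c("P0", "P65"))
  # duplicated gene id
  expect_error(cell_table(counts, c("Gal", "Gal", "g3"), meta, lad),
               "duplicated gene_ids")
  # metadata shorter than matrix
  expect_error(cell_table(counts, paste0("g", 1:3), meta[1, ], lad),
               "format error")
  # age label not in ladder
  bad <- meta; bad$age[1] <- "P99"
  expect_error(cell_table(counts, paste0("g", 1:3), bad, lad), "P99")
  # on-disk variant: cell TSV missing one row
  tab <- cell_table(counts, paste0("g", 1:3), meta, lad)
  dir <- withr::local_tempdir()
  write_cell_table(tab, dir)
  cells <- read.delim(file.path(dir, "cells.tsv"))
  write.table(cells[1, ], file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_cell_table(file.path(dir, "matrix.mtx"),
                               file.path(dir, "genes.tsv"),
                               file.path(dir, "cells.tsv"), lad),
               "format error")
})

test_that("qc_filter applies each nucleus filtering rule and is idempotent", {
  lad <- age_ladder(c("P0", "P65"))
  ng <- 300
  gid <- sprintf("g%03d", seq_len(ng))
  mk <- function(v) { stopifnot(length(v) == ng); v }
  # A: 300 total UMIs spread over 300 genes -> fails the UMI floor only
  a <- mk(rep(1, ng))
  # B: 1000 UMIs with 250 (25%) from one gene -> fails the top-gene rule
  b <- mk(c(250, rep(3, 250), rep(0, 49)))
  # C: 500 UMIs, 260 genes, max gene 50, no flagged UMIs -> kept
  cc <- mk(c(50, rep(2, 191), rep(1, 68), rep(0, 40)))
  # D: 500 UMIs over 261 genes with 60 mito (12% > 10%)
  d <- mk(c(rep(2, 180), rep(1, 80), rep(0, 30), 60, rep(0, 9)))
  # E: 515 UMIs with 15 IEG (2.9% > 1%)
  e <- mk(c(rep(2, 250), rep(0, 45), 15, rep(0, 4)))
  counts <- cbind(a, b, cc, d, e)
  stopifnot(colSums(counts) == c(300, 1000, 500, 500, 515))
  meta <- make_meta(5, ages = "P65")
  tab <- cell_table(counts, gid, meta, lad)
  params <- qc_params(flag_gene_lists = list(mito = "g291", IEG = "g296"))
  out <- suppressMessages(qc_filter(tab, params, verbose = FALSE))
  expect_identical(out$cell_meta$cell_id, "c3")
  removed <- attr(out, "qc_removed")
  expect_equal(unname(removed[c("umi", "top_gene", "mito", "IEG")]),
               c(1, 1, 1, 1))
  # idempotent: filtering twice equals filtering once
  twice <- suppressWarnings(qc_filter(out, params, verbose = FALSE))
  expect_equal(as.matrix(twice$counts), as.matrix(out$counts))
  # unknown flagged ids are ignored with a warning
  params2 <- qc_params(flag_gene_lists = list(mito = c("g291", "nope")))
  expect_warning(qc_filter(tab, params2, verbose = FALSE), "not in table")
})

test_that("lognormalize matches the log1p-CPX formula and keeps zeros", {
  lad <- age_ladder(c("P0", "P65"))
  counts <- cbind(c(1, 0, 3), c(0, 0, 0), c(2, 2, 0))
  tab <- cell_table(counts, c("g1", "g2", "g3"),
                    make_meta(3, "P65"), lad)
  norm <- lognormalize(tab)
  expect_equal(norm[1, 1], log(1 + 2500))
  expect_equal(norm[3, 1], log(1 + 7500))
  expect_true(all(norm[, 2] == 0))  # all-zero cell stays all-zero
  norm1 <- lognormalize(tab, scale_factor = 1)
  expect_equal(norm1[1, 3], log(1 + 0.5))
  expect_equal(norm1[2, 3], log(1 + 0.5))
  # zero pattern preserved
  expect_identical(as.matrix(norm) == 0, counts == 0,
                   ignore_attr = TRUE)
})

test_that("scale_genes centers, scales with n-1 sd, and clips", {
  m <- rbind(c(5, 5, 5), c(0, 2, 1))
  out <- scale_genes(m)
  expect_equal(out[1, ], c(0, 0, 0))          # zero-variance guard
  expect_equal(out[2, 1:2], c(-1, 1))         # (0,2,1): sd=1, centered
  m2 <- rbind(c(0, 2))
  expect_equal(scale_genes(m2)[1, ], c(-1 / sqrt(2), 1 / sqrt(2)))
  # clipping rule: a value standardizing to 12 is capped at 10
  expect_equal(scale_genes(rbind(c(0, 12)), center = 0, scale = 1)[1, ],
               c(0, 10))
  big <- rbind(c(rep(0, 199), 100))           # outlier standardizes ~14
  expect_equal(max(scale_genes(big)), 10)
})

test_that("pca matches a dense SVD oracle and its spectral properties", {
  set.seed(7)
  m <- matrix(rnorm(20 * 50), nrow = 20)      # genes x cells
  emb <- pca(m, 20)
  xc <- scale(t(m), center = TRUE, scale = FALSE)
  sv <- svd(xc)
  oracle <- sv$u %*% diag(sv$d)
  for (k in 1:20) {
    agree <- min(max(abs(emb$scores[, k] - oracle[, k])),
                 max(abs(emb$scores[, k] + oracle[, k])))
    expect_lt(agree, 1e-8)
  }
  # variance fractions nonincreasing, in [0,1]
  expect_true(all(diff(emb$variance_fractions) <= 1e-12))
  expect_true(all(emb$variance_fractions >= 0 &
                    emb$variance_fractions <= 1))
  # score columns mutually orthogonal
  g <- crossprod(emb$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # full reconstruction recovers the centered matrix
  expect_lt(max(abs(emb$scores %*% t(emb$rotation) - xc)), 1e-8)
  # rank-1 data: PC1 holds all variance
  line <- rbind(1:10, 2 * (1:10))
  expect_equal(pca(line, 2)$variance_fractions[1], 1)
  expect_error(pca(m, 21), "validation error")
})

test_that("select_hvg ranks genes by log-normalized variance", {
  set.seed(1)
  m <- rbind(rep(1, 10), rnorm(10, sd = 5), rnorm(10, sd = 0.1))
  expect_equal(select_hvg(m, 1), 2L)
  expect_equal(select_hvg(m, 5), 1:3)  # capped at available genes
})
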