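# shared fixtures and tiny oracles used across test files

lad6 <- function() age_ladder(c("P0", "P4", "P10", "P18", "P28", "P65"))

make_meta <- function(n, ages, sample_id = paste0("s", seq_len(n)),
                      sex = "F", genotype = "WT", cell_type = "T1",
                      region = "R1") {
  data.frame(cell_id = paste0("c", seq_len(n)),
             sample_id = rep_len(sample_id, n), age = rep_len(ages, n),
             sex = rep_len(sex, n), genotype = rep_len(genotype, n),
             cell_type = rep_len(cell_type, n),
             region = rep_len(region, n), stringsAsFactors = FALSE)
}

# textbook Welch two-sided t-test p-value (independent oracle)
welch_p <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(y) - mean(x)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(t), df)
}

# adjusted Rand index between two partitions
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_ij <- si * sj / n
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}
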