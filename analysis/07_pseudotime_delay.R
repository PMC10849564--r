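# Developmental delay: build the wild-type 20-PC principal path per cell
# type, project mutant and control cells onto it, and test mutant versus
# control per-sample mean pseudotime at each age.

source("analysis/_common.R")

table <- load_dataset()
genos <- unique(table$cell_meta$genotype)
mutant <- setdiff(genos, "WT")[1]
lad <- table$ladder

rows <- list()
for (age in c("P0", "P10", "P18", lad$adult)) {
  pd <- pseudotime_delay(table, "CT01", "WT", mutant, ages = age)
  gm <- pd$test$group_means
  rows[[age]] <- data.frame(
    age = age, control_mean = gm[["WT"]], mutant_mean = gm[[mutant]],
    difference = gm[[mutant]] - gm[["WT"]], p_value = pd$test$p_value)
  message(sprintf("CT01 at %s: WT %.2f vs %s %.2f, p = %.3g", age,
                  gm[["WT"]], mutant, gm[[mutant]], pd$test$p_value))
}
out <- do.call(rbind, rows)
rownames(out) <- NULL
write_tsv(out, "pseudotime_delay_CT01.tsv")

delayed <- out$age[out$p_value < 0.05 & out$difference < 0]
message("ages with significant mutant delay: ",
        if (length(delayed)) paste(delayed, collapse = ", ") else "none")
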