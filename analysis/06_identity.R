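# Identity mapping: soft-classify each younger age's cells against the
# adult reference profiles, apply the across-age assignment rules
# (0.8 / 0.5-with-2x), and quantify one-to-one mapping with the identity
# ratio per cell type.

source("analysis/_common.R")

table <- load_dataset()
wt <- subset_cells(table, table$cell_meta$genotype == "WT")
lad <- wt$ladder

adult <- subset_cells(wt, wt$cell_meta$age == lad$adult)
ref_prof <- celltype_profiles(scale_genes(lognormalize(adult)),
                              adult$cell_meta$cell_type)

rows <- list()
for (age in setdiff(lad$labels, lad$adult)) {
  query <- subset_cells(wt, wt$cell_meta$age == age)
  scores <- soft_classify(scale_genes(lognormalize(query)), ref_prof)
  labels <- assign_labels_acrossage(scores)
  pm <- prediction_matrix(scores, query$cell_meta$cell_type)
  ir <- identity_ratios(pm)
  rows[[age]] <- data.frame(
    age = age, cell_type = names(ir), identity_ratio = unname(ir),
    assigned_fraction = vapply(names(ir), function(ct) {
      i <- query$cell_meta$cell_type == ct
      mean(labels[i] != "unassigned")
    }, 0),
    correct_fraction = vapply(names(ir), function(ct) {
      i <- query$cell_meta$cell_type == ct
      mean(labels[i] == ct)
    }, 0))
}
out <- do.call(rbind, rows)
rownames(out) <- NULL
write_tsv(out, "identity_ratio_by_age.tsv")
for (age in unique(out$age)) {
  i <- out$age == age
  message(sprintf("%s -> adult: median identity ratio %.2f, %.0f%% correct",
                  age, median(out$identity_ratio[i]),
                  100 * mean(out$correct_fraction[i])))
}
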