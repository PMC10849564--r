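# Maturation trajectories: per cell type, the Manhattan distance between
# each age's centroid and the adult centroid in PC space, clamped monotone,
# staged and classified as gradual / intermediate / stepwise. Compares the
# assigned classes against the generator's truth and repeats the analysis
# split by sex.

source("analysis/_common.R")

table <- load_dataset()
wt <- subset_cells(table, table$cell_meta$genotype == "WT")

trajs <- maturation_trajectories(wt)
write_tsv(trajectory_table(trajs), "trajectories.tsv")
classes <- trajectory_class_table(trajs)
write_tsv(classes, "trajectory_classes.tsv")

truth <- read.delim(file.path(DATA_DIR, "truth_class.tsv"))
ok <- classes$class_label ==
  truth$true_class[match(classes$cell_type, truth$cell_type)]
message(sprintf("trajectory class recovered for %d / %d cell types",
                sum(ok), length(ok)))
message("class counts: ",
        paste(names(table(classes$class_label)),
              table(classes$class_label), sep = "=", collapse = ", "))

# adult-neighbor maturity for one cell type as the alternative measure
ct1 <- subset_cells(wt, wt$cell_meta$cell_type == "CT01")
emb <- embed_cells(ct1, n_components = 20)
fr <- adult_neighbor_fraction(emb, ct1$cell_meta$age, wt$ladder, k = 50)
write_tsv(data.frame(age = names(fr), adult_neighbor_fraction = fr,
                     scaled_cumulative = scaled_cumulative_fraction(fr)),
          "adult_neighbor_fraction_CT01.tsv")

# male-female trajectory comparison (distance curves per sex)
by_sex <- maturation_trajectories(wt, split_by = "sex")
cmp <- compare_trajectories(by_sex$F, by_sex$M)
write_tsv(data.frame(cell_type = rownames(cmp$difference),
                     cmp$difference, check.names = FALSE),
          "trajectory_sex_difference.tsv")
message(sprintf("male - female distance t-test p = %.3g", cmp$p_value))
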