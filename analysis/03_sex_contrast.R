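# Sex differences per cell type: inter/intra-sex sample-centroid distance
# ratios with t-test + BH across cell types, pseudobulk sexDEGs at the
# adult age, and cell-type proportions by sex.

source("analysis/_common.R")

table <- load_dataset()
wt <- subset_cells(table, table$cell_meta$genotype == "WT")

contrast <- contrast_all_celltypes(wt, "sex")
write_tsv(contrast, "sex_contrast.tsv")
message(sprintf("%d / %d cell types sex-different at BH 0.05",
                sum(contrast$p_adj < 0.05), nrow(contrast)))

# sexDEGs in the most affected cell type; samples are pooled across ages
# (this world's sex effects are on at every age) to reach a workable n,
# the same way the source design pools control samples to boost n
top_ct <- contrast$cell_type[which.max(contrast$ratio)]
sub <- subset_cells(wt, wt$cell_meta$cell_type == top_ct)
pb <- pseudobulk(sub)
sex_of <- tapply(sub$cell_meta$sex, sub$cell_meta$sample_id, `[`, 1L)
de <- de_test(pb, sex_of[colnames(pb)])
write_tsv(de, paste0("sexdeg_", top_ct, ".tsv"))
message(sprintf("%s: %d sexDEGs at adjusted p < 0.05 (%d samples)",
                top_ct, sum(de$significant), ncol(pb)))

prop <- celltype_proportions(wt)
write_tsv(data.frame(sample_id = rownames(prop), prop,
                     check.names = FALSE), "celltype_proportions.tsv")
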