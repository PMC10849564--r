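# Developmental gene programs: devDEGs per cell type across ages (FDR<5%),
# sharing classification across cell types, trend fitting + hierarchical
# trend clustering, module scores of the maturation gene set and its
# refinement score between P10 and adult.

source("analysis/_common.R")

table <- load_dataset()
wt <- subset_cells(table, table$cell_meta$genotype == "WT")
cts <- sort(unique(wt$cell_meta$cell_type))

devs <- lapply(cts, function(ct) dev_de(wt, ct))
names(devs) <- cts
sets <- lapply(devs, function(d) d$gene_id[d$significant])
write_tsv(data.frame(cell_type = cts,
                     n_devdeg = vapply(sets, length, 0L)),
          "devdeg_counts.tsv")
sharing <- classify_sharing(sets)
write_tsv(sharing, "devdeg_sharing.tsv")
message(sprintf("devDEG sharing: %d shared, %d intermediate, %d specific",
                sum(sharing$label == "shared"),
                sum(sharing$label == "intermediate"),
                sum(sharing$label == "specific")))

# fitted expression trends of CT01's devDEGs, clustered by shape
ct1 <- subset_cells(wt, wt$cell_meta$cell_type == "CT01")
pb <- pseudobulk(ct1)
age_of <- tapply(ct1$cell_meta$age, ct1$cell_meta$sample_id, `[`, 1L)
lc <- log2(sweep(pb, 2, pmax(colSums(pb), 1), `/`) * 1e6 + 1)
deg <- sets$CT01
trends <- t(vapply(deg, function(g) {
  fit_trend(lc[g, ], age_of[colnames(pb)], wt$ladder)
}, numeric(length(wt$ladder$labels))))
cl <- cluster_trends(trends, 4)
write_tsv(data.frame(gene_id = deg, cluster = cl, trends,
                     check.names = FALSE), "devdeg_trends_CT01.tsv")
message(sprintf("clustered %d CT01 devDEG trends into %d shapes",
                nrow(trends), length(unique(cl))))

# module score of the true maturation gene set, z-scored by age
mat_set <- read.delim(file.path(DATA_DIR,
                                "truth_maturation_genes.tsv"))$gene_id
norm <- lognormalize(ct1)
score <- module_score(norm, mat_set, seed = 1)
z <- aggregate_score_by_age(score, ct1$cell_meta$age, wt$ladder)
write_tsv(data.frame(age = names(z), module_score_z = z),
          "module_score_maturation_CT01.tsv")

rs <- refinement_score_for_set(wt, mat_set, young_age = "P10")
message(sprintf(
  "refinement score (maturation set, P10 vs adult): %.3f (%d / %d combos)",
  rs$score, rs$n_significant, rs$n_expressed))
write_tsv(data.frame(gene_set = "maturation", score = rs$score,
                     n_significant = rs$n_significant,
                     n_expressed = rs$n_expressed),
          "refinement_score.tsv")
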