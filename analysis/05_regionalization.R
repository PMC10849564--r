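# Regionalization: per-age cell-type profile correlations, within-region
# means normalized to the adult age, and region marker genes at the first
# and adult ages.

source("analysis/_common.R")

table <- load_dataset()
wt <- subset_cells(table, table$cell_meta$genotype == "WT")

regions <- vapply(split(wt$cell_meta$region, wt$cell_meta$cell_type),
                  `[`, "", 1L)
corr <- celltype_correlation_by_age(wt)
trend <- within_region_correlation(corr, regions, wt$ladder$adult)
write_tsv(trend, "region_trend.tsv")
for (r in unique(trend$region)) {
  v <- trend$normalized[trend$region == r]
  message(sprintf("region %s: normalized correlation %s (nondecreasing: %s)",
                  r, paste(sprintf("%.2f", v), collapse = " "),
                  all(diff(v) >= 0)))
}

adult <- subset_cells(wt, wt$cell_meta$age == wt$ladder$adult)
mk <- find_region_markers(adult)
write_tsv(do.call(rbind, lapply(names(mk), function(r) {
  if (!nrow(mk[[r]])) return(NULL)
  cbind(region = r, mk[[r]])
})), "region_markers_adult.tsv")
message("adult region markers: ",
        paste(names(mk), vapply(mk, nrow, 0L), sep = "=", collapse = ", "))

co <- marker_correlation_to_adult(wt, unlist(lapply(mk, `[[`, "gene_id")))
write_tsv(data.frame(age = names(co), correlation_to_adult = co),
          "marker_correlation_to_adult.tsv")
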