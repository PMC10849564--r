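# Simulate the developmental single-nucleus study and write it to disk in
# the standard on-disk schema (MatrixMarket counts + TSV metadata) together
# with the generator's ground-truth tables.

source("analysis/_common.R")

config <- analysis_config()
sim <- simulate_dataset(config)

if (!dir.exists(DATA_DIR)) dir.create(DATA_DIR, recursive = TRUE)
write_cell_table(sim$table, DATA_DIR)
write_sim_truth(sim$truth, DATA_DIR)

message(sprintf("simulated %d genes x %d cells: %d cell types, %d ages, %s",
                n_genes(sim$table), n_cells(sim$table),
                nrow(config$cell_types),
                length(config$ladder$labels),
                paste(names(config$genotype_delays), collapse = " / ")))
message(sprintf("mean library size %.0f UMIs/cell",
                mean(library_sizes(sim$table))))
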