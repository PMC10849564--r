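# Shared configuration for the numbered analysis drivers. Every script can
# be run from the repository root with:  Rscript analysis/<script>.R

suppressPackageStartupMessages(library(devtraj))

DATA_DIR <- "results/data"
RESULTS_DIR <- "results"

analysis_ladder <- function() poa_age_ladder()

# The simulated study: 12 cell types (4 per maturation class) in 3
# sub-regions, profiled at 8 ages with 2 samples per sex per age, for a
# wild-type and a delayed mutant genotype. The gene panel is marker-rich
# (15 markers per cell type) so that cell types are identifiable the way
# real, well-annotated types are.
analysis_config <- function(seed = 20260918) {
  ladder <- analysis_ladder()
  sim_config(
    ladder = ladder,
    cell_types = sim_cell_types(4, 4, 4, ladder = ladder),
    n_genes = 500, n_marker_genes = 180,
    cells_per_sample_per_type = 15,
    genotype_delays = c(WT = 0L, Trpc2KO = 1L),
    seed = seed
  )
}

load_dataset <- function() {
  read_cell_table(file.path(DATA_DIR, "matrix.mtx"),
                  file.path(DATA_DIR, "genes.tsv"),
                  file.path(DATA_DIR, "cells.tsv"),
                  analysis_ladder())
}

write_tsv <- function(x, name) {
  if (!dir.exists(RESULTS_DIR)) dir.create(RESULTS_DIR, recursive = TRUE)
  utils::write.table(x, file.path(RESULTS_DIR, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("wrote ", file.path(RESULTS_DIR, name))
}
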