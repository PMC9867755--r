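#!/usr/bin/env Rscript
# Stage 1: generate the default two-condition synthetic dataset.
#
# 500 cells per condition x stage (4000 total), 600 genes, organoid jitter
# sigma 0.6 vs native 0.3, 15% organoid stage mis-assignment, 10 planted
# markers per type (ln-fold 1.5) of which 2 per type carry organoid-only
# perturbations (ln-fold 1.0). Writes the 10x-style bundle plus ground
# truth under results/analysis/.

library(retcomp)

seed <- 42L
outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_retina(synth_config(seed = seed))
write_cell_table(sim$table, file.path(outdir, "synthetic"))
write.table(sim$truth$cells, file.path(outdir, "ground_truth_cells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$markers, file.path(outdir, "ground_truth_markers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$perturbations,
            file.path(outdir, "ground_truth_perturbations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gmt(truth_signatures(sim$truth),
          file.path(outdir, "signatures.gmt"))
writeLines(as.character(seed), file.path(outdir, "seed.txt"))

cat("cells:", sim$table$n_cells, " genes:", sim$table$n_genes, "\n")
cat("per condition x stage:\n")
print(table(sim$table$condition, sim$table$stage))
cat("planted markers:", nrow(sim$truth$markers),
    " perturbations:", nrow(sim$truth$perturbations), "\n")
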