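#!/usr/bin/env Rscript
# Stage 6: cross-condition expression-profile correlation.
#
# For every planted marker gene, the per-type mean fraction-of-UMI profile
# (across the 13 cell types) is computed separately in native and organoid
# cells and correlated per gene (Pearson). Unperturbed genes should
# correlate near 1; the planted organoid perturbations drag their genes
# down, mimicking the conserved-vs-perturbed split used to judge whether
# the organoid models a gene's native expression.

library(retcomp)

outdir <- "results/analysis"
tab <- load_cell_table(file.path(outdir, "synthetic/matrix.mtx"),
                       file.path(outdir, "synthetic/genes.tsv"),
                       file.path(outdir, "synthetic/barcodes.tsv"),
                       file.path(outdir, "synthetic/metadata.tsv"))
markers <- read.delim(file.path(outdir, "ground_truth_markers.tsv"))
perts <- read.delim(file.path(outdir, "ground_truth_perturbations.tsv"))
cfg <- pipeline_config(rng_seed = as.integer(
  readLines(file.path(outdir, "seed.txt"))))
expr <- normalize_fraction_umi(tab)

split_expr <- function(sel) {
  e <- expr
  e$values <- expr$values[sel, , drop = FALSE]
  e$cell_ids <- expr$cell_ids[sel]
  e$zero_count_cells <- intersect(expr$zero_count_cells, e$cell_ids)
  e
}
nat <- tab$condition == "native"
genes <- gene_list("markers", markers$gene)
pa <- mean_profile_matrix(split_expr(nat), tab$cell_type[nat], genes)
pb <- mean_profile_matrix(split_expr(!nat), tab$cell_type[!nat], genes)
pc <- profile_correlation(pa, pb, r_threshold = cfg$r_threshold)

write.table(pc$per_gene, file.path(outdir, "correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(median_r = pc$median_r, n_above = pc$n_above,
                          percent_above = pc$percent_above,
                          n_zero_variance = pc$n_zero_variance),
                     file.path(outdir, "correlation_summary.json"),
                     auto_unbox = TRUE, digits = NA)

r <- setNames(pc$per_gene$r, pc$per_gene$gene)
clean <- setdiff(markers$gene, perts$gene)
cat("genes correlated:", nrow(pc$per_gene), "\n")
cat(sprintf("median r: %.3f; r > %.2f for %d genes (%.0f%%)\n",
            pc$median_r, cfg$r_threshold, pc$n_above, pc$percent_above))
cat(sprintf("median r unperturbed %.3f vs perturbed %.3f\n",
            median(r[clean], na.rm = TRUE),
            median(r[intersect(perts$gene, names(r))], na.rm = TRUE)))
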