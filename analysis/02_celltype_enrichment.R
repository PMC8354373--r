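#!/usr/bin/env Rscript
## Stage 2 — expression-weighted cell-type enrichment of the target list.
##
## Computes the gene x cell-type specificity matrix from the simulated
## single-cell counts, bins the background by transcript length x GC
## deciles, and tests whether the target list's summed specificity in each
## cell type exceeds covariate-matched bootstrap lists. The planted markers
## should make exactly one cell type ("neuron") significant after BH
## correction.

suppressMessages(library(dytnet))
seed <- 101L

cells <- simulate_cell_profiles(2000, c(neuron = 250, astrocyte = 250,
                                        oligodendrocyte = 250,
                                        microglia = 250),
                                n_markers_per_type = 50, fold_change = 8,
                                dispersion = 0.5, seed = seed)
target <- gene_list("target", sprintf("G%05d", 1:30))

spec <- compute_specificity(cells$counts, cells$cell_meta)
write_specificity(spec, "scratch/analysis_data/specificity.tsv")
bins <- match_covariate_bins(cells$gene_annot, rownames(spec),
                             n_quantiles = 10)
res <- bootstrap_enrichment(spec, target, reps = 10000, bins = bins,
                            seed = seed + 10L)
write.table(res, "results/02_ewce.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- flag_significant(res, 0.05)
cat("\nEWCE over", nrow(res), "cell types,", attr(res, "reps"),
    "bootstrap replicates:\n")
print(res, digits = 3)
cat("\nSignificant after BH (q < 0.05):", paste(sig, collapse = ", "), "\n")
cat("Finding: the target list is specifically enriched in the cell type",
    "carrying its planted markers, with negative (depleted) effect sizes",
    "floored to zero elsewhere.\n")
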