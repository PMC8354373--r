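#!/usr/bin/env Rscript
## Stage 5 — stratified LD-score heritability of the enriched module.
##
## Builds a binary SNP annotation from the kME >= 0.5 genes of the
## target-enriched putamen module (gene intervals extended by 100 kb, SNPs
## with MAF > 5%), then regresses each trait's chi-square statistics on the
## baseline + module LD scores with block-jackknife SEs. The trait whose
## summary statistics carry a planted module tau should pass the Bonferroni
## threshold 0.05 / (modules x GWAS); the null trait should not.

suppressMessages(library(dytnet))
seed <- 101L

tissues <- simulate_tissue_expression(
  1000, c("putamen", "cortex", "cerebellum"), 150,
  blocks = list(list(size = 60, strength = 0.8, tissue = "putamen"),
                list(size = 50, strength = 0.8, tissue = "all"),
                list(size = 40, strength = 0.7, tissue = "all")),
  seed = seed + 1L)
net <- build_network(tissues$expr$putamen, beta = 6)
target <- sprintf("G%05d", 1:30)

ld <- simulate_ld_reference(4000, 400, block_size = 20,
                            within_block_rho = 0.6, chrom_length = 4e7,
                            seed = seed + 2L)
coords <- simulate_gene_coordinates(1000, chrom_length = 4e7,
                                    seed = seed + 3L)

## summary statistics exactly as generated in stage 1
block1 <- names(tissues$truth$block)[tissues$truth$block == 1L]
truth_annot <- build_gene_annotation(
  block1, setNames(rep(1, length(block1)), block1), coords, ld$map)
sim_annot <- cbind(base = rep(1L, nrow(ld$map)), module = truth_annot)
rownames(sim_annot) <- ld$map$snp
taus <- c(trait_linked = 5e-5, trait_null = 0)
gwas <- lapply(names(taus), function(gw)
  simulate_sumstats(ld, sim_annot, c(base = 0, module = taus[[gw]]),
                    N = 10000, seed = seed + 4L + match(gw, names(taus)))$sumstats)
names(gwas) <- names(taus)

## annotation from the detected module, kME-filtered
carrier <- names(which.max(table(net$labels[target])))
members <- names(net$labels)[net$labels == carrier]
mod_annot <- build_gene_annotation(members, net$kme[members, carrier],
                                   coords, ld$map, kme_threshold = 0.5,
                                   flank_bp = 1e5, maf_min = 0.05)
cat(sprintf("Detected module '%s': %d genes, %d after kME filter, %d SNPs annotated\n",
            carrier, length(members),
            sum(net$kme[members, carrier] >= 0.5), sum(mod_annot)))

baseline <- cbind(base = rep(1L, nrow(ld$map)))
rownames(baseline) <- ld$map$snp
bat <- run_heritability_battery(setNames(list(mod_annot),
                                         paste0("putamen.", carrier)),
                                gwas, ld, baseline, n_blocks = 100)
write.table(bat, "results/05_heritability.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nStratified LD-score regression (Bonferroni threshold",
    format(attr(bat, "threshold"), digits = 3), "):\n")
print(bat, digits = 3)
cat("\nFinding: the module annotation carries the planted per-SNP",
    "heritability of the linked trait (Bonferroni-significant one-tailed",
    "coefficient p) and shows no signal for the null trait.\n")
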