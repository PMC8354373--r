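# dytnet

Do the genes of a Mendelian disease converge on particular brain cell types
and tissue-specific co-expression modules — and do those modules carry the
heritability of related complex traits? `dytnet` implements this
systems-biology workflow end to end for curated gene lists, with the 28
confirmed dystonia (DYT) genes packaged as the worked example. It is aimed
at statistical geneticists and neurogenomics researchers who want each
stage of such an analysis as a tested, seedable R function rather than a
chain of external tools.

The five stages, each exposed as package functions and driven by the
numbered scripts under `analysis/`:

1. **Specificity & EWCE** — gene × cell-type specificity
   `s(g,c) = x̄_gc / Σ_c' x̄_gc'` from annotated single-cell counts, then
   expression-weighted cell-type enrichment: the target list's summed
   specificity per cell type against bootstrap lists matched on transcript
   length × GC decile bins, reported as standard deviations from the
   bootstrap mean (negatives floored to 0), with add-one p-values and BH
   correction across cell types.
2. **Signed co-expression networks** — adjacency `((1+r)/2)^β`, topological
   overlap (TOM), average-linkage clustering of `1 − TOM` with a static cut,
   k-means refinement over module eigengenes, and kME (module membership).
3. **Module enrichment** — one-tailed hypergeometric over-representation of
   the target list in every module across all networks, BH-adjusted jointly;
   generic GMT over-representation with a minimum in-background set size.
4. **Preservation** — Z-summary (mean of permutation Z scores of
   within-module density and intramodular-connectivity agreement) of
   reference-tissue modules in other tissues; > 10 strong, 2–10
   weak-moderate, < 2 none.
5. **Stratified LD-score regression** — binary SNP annotations from
   kME ≥ 0.5 module genes (±100 kb, MAF > 5%), LD scores
   `ℓ(j,C) = Σ_k r̃²(j,k)` with the unbiased `r²` adjustment, weighted
   regression of `χ²` on `N·ℓ` with delete-one block-jackknife SEs,
   one-tailed coefficient p, and the Bonferroni family threshold
   `0.05/(modules × GWAS)`.

A synthetic-data layer (`simulate_*`) generates every input with planted
ground truth — NB single-cell counts with marker genes, multi-tissue
expression with planted correlation blocks (one tissue-specific), an LD
panel with exact block correlation, and GWAS summary statistics drawn from
the stratified heritability model — so the whole pipeline is verifiable at
desk scale. See `vignettes/dystonia-convergence.Rmd` for the methods in
detail.

## Worked example

Enrichment of a 30-gene target list in simulated single-cell data whose
first cell type carries the planted markers:

```r
library(dytnet)
cells <- simulate_cell_profiles(2000, c(neuron = 250, astrocyte = 250,
                                        oligodendrocyte = 250, microglia = 250),
                                n_markers_per_type = 50, fold_change = 8,
                                dispersion = 0.5, seed = 101)
spec <- compute_specificity(cells$counts, cells$cell_meta)
bins <- match_covariate_bins(cells$gene_annot, rownames(spec))
res  <- bootstrap_enrichment(spec, gene_list("target", sprintf("G%05d", 1:30)),
                             reps = 10000, bins = bins, seed = 111)
print(res, digits = 3)
#>         cell_type observed boot_mean boot_sd sd_from_mean display     p     q
#> 1          neuron    21.75      8.18   0.703        19.30    19.3 1e-04 4e-04
#> 2       astrocyte     2.77      7.19   0.461        -9.59     0.0 1e+00 1e+00
#> 3 oligodendrocyte     2.71      7.40   0.533        -8.79     0.0 1e+00 1e+00
#> 4       microglia     2.76      7.24   0.486        -9.21     0.0 1e+00 1e+00
flag_significant(res)
#> [1] "neuron"
```

The target list scores 21.75 summed specificity in neurons, 19.3 bootstrap
standard deviations above the covariate-matched null (q = 4 × 10⁻⁴); the
other types are depleted (displayed as 0) — the planted convergence on one
cell type, recovered. The curated gene list itself:

```r
dyt_genes()
#> <gene_list> DYT genes: 28 genes
intersect_genes(dyt_genes(), c("ADCY5","ANO3","KCTD17","HPCA",
                               "PRRT2","SCN8A","KCNA1","CACNA1A"))$n
#> [1] 8
```

Run the full narrative analysis (simulation → EWCE → networks →
preservation → heritability, each printing its finding and writing tables
under `results/`):

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

or as one orchestrated, seeded pipeline from a YAML config via
`validate_config()` + `run_all()`.

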