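---
title: "Methods: cell-type enrichment, co-expression modules and partitioned heritability for curated gene lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type enrichment, co-expression modules and partitioned heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dytnet` implements a five-stage systems-biology workflow for asking whether
a curated list of Mendelian disease genes — the packaged example is the 28
confirmed dystonia (DYT) genes, spanning isolated, combined and paroxysmal
clinical classes — converges on particular brain cell types and on
tissue-specific co-expression modules, and whether those modules carry
heritability of complex traits. This vignette is the package's own account
of each statistical component: the model, its assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Specificity and expression-weighted cell-type enrichment

The **specificity** of gene $g$ in cell type $c$ is

$$s(g,c) = \frac{\bar x_{g,c}}{\sum_{c'} \bar x_{g,c'}},$$

the proportion of the gene's total (across-type) mean expression
attributable to $c$; rows sum to one, 1 means exclusive expression. Per-type
means use all cells of the type including zeros. Genes whose per-type means
are all zero are dropped (0/0 is undefined and such genes carry no signal)
rather than assigned a uniform row. Whether counts are depth-normalized
before averaging is deliberately left to the caller: the matrix is taken as
given, and the normalization choice should be made with the upstream
single-cell processing, not silently inside this package.

The enrichment test (`bootstrap_enrichment()`) scores a target list by its
summed specificity per cell type and compares it against random background
lists of the same size. The sum and the mean give identical p-values at
fixed list size; the sum is reported. Replicates are drawn
**covariate-matched**: background genes are binned by the joint
transcript-length × GC deciles (`match_covariate_bins()`, default 10
quantiles per covariate, so a 10 × 10 joint grid), and each replicate
replaces every target gene with a random gene from the same bin. This
controls the tendency of long, GC-atypical genes to be better captured and
hence to score high for artefactual reasons. Matching details the
literature leaves open were fixed as follows: sampling is per-target-gene
within its own bin, without replacement within a replicate where the bin
allows, falling back to with-replacement (with a logged warning) in
exhausted bins. Binning is only meaningful when bins stay coarse relative
to the background; with only a few genes per joint bin the replicates
re-draw the target genes themselves and the test degenerates toward the
null, so the default deciles assume a background of a few thousand genes.

P-values use add-one smoothing, $p = (1 + \#\{\text{boot} \ge
\text{obs}\})/(R+1)$, which keeps them strictly positive and valid at
finite $R$; an exact mode enumerates all $\binom{n}{m}$ targets for tiny
backgrounds and then reports the unsmoothed tail proportion. The effect
size is the number of bootstrap standard deviations the observed score sits
above the bootstrap mean; negative values indicate depletion and are
floored to 0 for display. A constant bootstrap distribution (e.g. target =
background) defines the effect as 0. BH correction is applied across cell
types. Defaults: 100,000 replicates in production, 2,000 in the test
configuration; seeds are mandatory everywhere.

## Signed co-expression networks

Per tissue, the network is built from the Pearson correlation $r_{ij}$ of
gene profiles across samples:

* signed adjacency $a_{ij} = ((1 + r_{ij})/2)^\beta$, mapping
  anticorrelation to 0 — "signed" because strong negative correlation is
  *not* connectivity;
* topological overlap
  $\mathrm{TOM}_{ij} = (\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}) /
  (\min(k_i,k_j) + 1 - a_{ij})$, which smooths the adjacency by
  shared-neighbor structure;
* average-linkage hierarchical clustering of $1 - \mathrm{TOM}$, cut at a
  single static height; clusters below the minimum size (default 30)
  become "grey" (unassigned), and surviving modules are labeled from a
  fixed color sequence by decreasing size, so labels are deterministic.

The soft power $\beta$ can be fixed (tests use $\beta = 6$) or selected by
`pick_soft_power()` as the smallest candidate whose scale-free topology fit
— the signed $R^2$ of log-frequency against log-connectivity over ten
equal-width connectivity bins — reaches 0.8.

Two choices deserve emphasis. First, a *static* cut height is used instead
of a dynamic tree-cut; the k-means refinement below dominates the final
assignments, and a single cut keeps the stage fully testable. On signed
TOM dissimilarities at $\beta = 6$ the merge heights of unrelated genes
concentrate near 0.97–0.98, so the default cut of 0.92 separates planted
correlation blocks across strengths 0.6–0.8 while leaving noise genes
grey; a cut at 0.99 would merge the whole tree into one module. Second,
the k-means refinement (`kmeans_refine()`, default 30 iterations) is a
declared reconstruction: eigengenes act as centroids, every assigned gene
moves to the module of its highest kME, undersized modules dissolve to
grey, and iteration stops early at a fixed point. The exact refinement
variant used alongside published co-expression catalogues is not specified
to this level of detail anywhere we could verify; the reconstruction is
monotone in the natural objective $\sum_g (1 - \mathrm{kME}_{g,\ell(g)})$
on planted data, which the tests track.

The **module eigengene** is the first principal component of the module's
per-gene standardized expression, unit-norm and sign-anchored so its mean
correlation with members is positive; **kME** (module membership) is the
correlation of a gene with an eigengene, computed for *all* genes
including grey ones, because the annotation stage filters on kME ≥ 0.5 and
a gene's membership evidence should not depend on its label.

## Module enrichment and preservation

Over-representation of a target list in a module is the one-tailed
hypergeometric upper tail given the background universe; the test family
is *all* modules across all supplied networks jointly, BH-adjusted,
mirroring the study design of testing a couple of hundred modules over ten
brain regions at once. The background defaults to the union of genes in
the tested networks — the genome is not a defensible universe when the
networks were built on a filtered gene set. GMT-based over-representation
(`ora_gmt()`) excludes sets with fewer than three in-background members
before testing, so tiny terms do not enter the family.

Preservation of a module defined in a reference tissue is quantified in a
test tissue by a two-statistic composite: mean within-module signed
adjacency (density) and the correlation of intramodular connectivity
vectors between tissues (connectivity). Each is standardized against
random gene sets of the same size (default 200 permutations, 50 in test
configurations; draws are uniform from the shared universe and do not
exclude module members), and the **Z-summary** is the mean of the two Z
scores, classified by the conventional thresholds: > 10 strong, 2–10 weak
to moderate, < 2 none (boundaries fall to the lower category). The full
seven-statistic composite of the reference implementation is intentionally
not reproduced: density and connectivity are the canonical representatives
of its two statistic families, and the 2/10 thresholds calibrate the same
way. One consequence of the synthetic data's equicorrelated blocks is that
their connectivity profile is flat, so the connectivity Z is uninformative
there and the density Z carries the decision; modules with hub structure
(graded loadings) engage both statistics, and the tests exercise that case
explicitly.

## Stratified LD-score regression

Per-SNP heritability contributions of annotations are estimated from the
model $E[\chi^2_j] = 1 + N \sum_C \tau_C\, \ell(j,C)$, where the LD score
$\ell(j,C) = \sum_{k \in C,\, |pos_k - pos_j| \le w} \tilde r^2_{jk}$ uses
the unbiased adjustment $\tilde r^2 = r^2 - (1 - r^2)/(n-2)$ from an
$n$-individual reference panel. The window $w$ defaults to 1 Mb of
physical distance — a stand-in for the conventional 1 cM, since the
synthetic maps carry no genetic distance. Module annotations are binary:
SNPs with MAF > 5% falling within 100 kb of the (0-based, half-open,
zero-clipped) extended coordinates of the module's kME ≥ 0.5 genes.
*Signed* kME is used for the filter; whether the published filter used
signed or absolute membership is not stated, and signed is the
conservative reading of "membership ≥ 0.5". Long-range LD regions can be
excluded from the regression (`exclude_region()`); excluded SNPs still act
as LD partners in the scores, mirroring the reference implementation's
treatment.

The regression is weighted least squares of $\chi^2$ on $\{N \ell(j,C)\}$
plus an intercept, one target category at a time on top of the baseline
model, with weights $1/\max(1, \ell_{base})^2$ as a simple
heteroskedasticity proxy and no $\chi^2$ truncation (a cap is exposed in
the reference method; here it is simply off). Standard errors come from a
delete-one block jackknife over contiguous equal-count SNP blocks in map
order (default 200 blocks), and inference is one-tailed on the coefficient
z-score — only positive heritability contributions are of interest.
Multiple testing across a battery uses the Bonferroni threshold
$\alpha/(\text{modules} \times \text{GWAS})$; "nominal" means $p < 0.05$
without passing Bonferroni. In null simulations the one-tailed rejection
rate at 0.05 sits near 0.035–0.045 — mildly conservative, driven by the
jackknife's slight SE inflation at 200 blocks — and planted coefficients
of $5 \times 10^{-5}$ at $N = 10^4$ over 8,000 SNPs are recovered with
relative bias under 2% and essentially full power.

## The synthetic-data layer

Every input is generated with planted ground truth, making each stage's
operating characteristics verifiable without any external download:

* **Single-cell counts**: negative binomial with log-normal baseline means
  (median ≈ 0.8 counts, log-sd 1.1) and dispersion 0.5 — typical of
  droplet-style data at gene level; each cell type receives 50 disjoint
  marker genes whose mean is multiplied by a fold change (8 in the study
  conditions) in that type only, so a marker's expected specificity is
  $8/(8+3) \approx 0.73$ against a 0.25 background for four types.
  Transcript length and GC are drawn mildly correlated with the baseline
  mean so covariate matching is a non-vacuous control.
* **Tissue expression**: planted blocks follow a single-factor model with
  loading $\sqrt{s}$, giving expected within-block correlation $s$
  (study conditions: blocks of 60/50/40 genes at $s$ = 0.7–0.8 over 150
  samples, matching post-QC brain-bank cohort sizes); one block's loadings
  are zeroed outside its home tissue to emulate a tissue-specific
  signature. Blocks are equicorrelated — real modules additionally carry
  hub structure, which is why module *detection* and *density*
  preservation, not connectivity preservation, are what passing tests
  certify on this generator.
* **LD panel**: haplotypes copy a per-block core with probability
  $\sqrt{\rho}$, which makes the expected pairwise dosage correlation
  within a 20-SNP block exactly $\rho$ (0.6 in the study conditions, 500
  individuals) and zero across blocks — chosen over a Gaussian-copula
  model precisely because the latter attenuates the realized correlation
  below its latent parameter.
* **Summary statistics**: z-scores are drawn independently from
  $N(0, \sqrt{1 + N\sum_C \tau_C \ell(j,C)})$ — the exact generative
  inverse of the estimator, so parameter recovery is a clean test of the
  regression rather than of an asymptotic approximation. What this does
  *not* emulate: correlated $\chi^2$ across SNPs in LD beyond what the
  mean model induces, sample overlap, or confounding inflation of the
  intercept.

What passing on this data does **not** show about real data: robustness to
mouse–human orthologue filtering (the synthetic namespace is shared, so
the published 1:1-orthologue restriction has no counterpart here), to
depth-normalization choices, to genetic (cM) distance, to allele-matching
QC of real summary statistics, or to modules whose correlation structure
departs from single-factor blocks.

## Scale, determinism and degenerate inputs

Every stochastic function takes an explicit seed and is a pure function of
its arguments; the pipeline driver (`run_all()`) refuses configurations
that omit a seed for any enabled stochastic stage and writes a
byte-stable JSON report. Problem sizes used throughout the test-scale
configurations — 2,000 genes × 1,000 cells for enrichment, 1,000 genes ×
150 samples per tissue for networks (the package targets desk-scale
networks of ≤ 5,000 genes; no block-wise approximation is provided), 8,000
SNPs × 500 panel individuals for heritability — were chosen as the
smallest sizes at which the planted effects operate in their asymptotic
regime, and the full suite exercises them in minutes on one CPU.

Degenerate cases are defined, not accidental: constant bootstrap
distributions give effect 0 and $p = 1$; zero-variance genes are an error
in network construction (they have no correlation structure) and an error
in eigengene computation; monomorphic SNPs are an error in LD scoring;
permutation nulls with zero spread mark the module's Z as degenerate
rather than dividing by zero; boundary values fall deterministically (kME
exactly 0.5 is included; Z-summary exactly 2 or 10 classifies to the
lower category; annotation intervals are half-open so an end coordinate is
excluded).

## Known limitations

The static cut height, the specific k-means variant, the two-statistic
Z-summary composite, the regression weighting, and the BH substitution for
set-counting corrections in ontology enrichment are all declared
reconstructions of under-specified published procedure, calibrated against
planted truth rather than against the original implementations. Cell-type
hierarchies (level-2 subtypes), consensus networks across tissues,
median-rank preservation, genetic-map support and heritability *enrichment*
partitions (beyond the per-SNP coefficient $\tau$) are out of scope.
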