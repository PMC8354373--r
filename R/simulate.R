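#' Simulate gene coordinates with transcript length and GC content
#'
#' Lays `n_genes` genes on a single chromosome with uniform lengths in
#' `[min_len, max_len]` (genes may overlap; the layout is deliberately
#' non-pathological rather than realistic). Coordinates are 0-based,
#' half-open. GC fraction is drawn uniformly unless supplied downstream.
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bp.
#' @param min_len,max_len Transcript length bounds in bp.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param gene_names Optional symbol vector (default `g0001`, ...).
#' @return Data frame: `gene`, `chrom`, `start`, `end`, `tx_length`, `gc`.
#' @export
simulate_gene_coordinates <- function(n_genes, chrom_length = 2.5e8,
                                      min_len = 1e3, max_len = 1e5,
                                      seed = 1, gene_names = NULL) {
  if (max_len >= chrom_length) dn_stop("max_len must be < chrom_length")
  set.seed(seed)
  if (is.null(gene_names))
    gene_names <- sprintf("G%05d", seq_len(n_genes))
  len <- round(stats::runif(n_genes, min_len, max_len))
  start <- floor(stats::runif(n_genes, 0, chrom_length - len))
  data.frame(gene = gene_names, chrom = "1",
             start = start, end = start + len,
             tx_length = len,
             gc = stats::runif(n_genes, 0.3, 0.7),
             stringsAsFactors = FALSE)
}

#' Simulate single-cell expression profiles with planted marker genes
#'
#' Counts follow a negative-binomial model with gene-level baseline means
#' (log-normal across genes) and a common dispersion. Each cell type gets a
#' disjoint set of planted marker genes whose mean is multiplied by
#' `fold_change` in that type only, so the expected specificity of a marker
#' in its own type is `fold_change / (fold_change + k - 1)` for `k` types.
#' Transcript length and GC are drawn with mild positive correlation to the
#' baseline mean, so covariate-matched bootstrap sampling is a non-vacuous
#' control downstream.
#'
#' @param n_genes Number of genes.
#' @param cell_types Named integer vector: cells per type.
#' @param n_markers_per_type Markers planted per cell type.
#' @param fold_change Multiplicative marker effect (>= 1).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed Integer seed.
#' @return List: `counts` (genes x cells), `cell_meta` (cell_id, cell_type),
#'   `gene_annot` ([simulate_gene_coordinates()] table with covariates tied
#'   to expression), `truth` (markers per type, fold_change, dispersion,
#'   baseline means).
#' @export
simulate_cell_profiles <- function(n_genes, cell_types, n_markers_per_type,
                                   fold_change = 8, dispersion = 0.5,
                                   seed = 1) {
  k <- length(cell_types)
  if (k < 2L) dn_stop("need at least 2 cell types")
  if (is.null(names(cell_types))) names(cell_types) <- paste0("type", seq_len(k))
  if (n_markers_per_type * k > n_genes)
    dn_stop("n_markers_per_type x n cell types exceeds n_genes")
  if (fold_change < 1) dn_stop("fold_change must be >= 1")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  mu0 <- exp(stats::rnorm(n_genes, mean = log(0.8), sd = 1.1))
  # markers occupy the leading gene indices, in type order; disjoint by design
  markers <- lapply(seq_len(k), function(i)
    genes[((i - 1L) * n_markers_per_type + 1L):(i * n_markers_per_type)])
  names(markers) <- names(cell_types)

  type_of_cell <- rep(names(cell_types), times = cell_types)
  n_cells <- length(type_of_cell)
  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(genes, sprintf("C%05d", seq_len(n_cells))))
  for (t in names(cell_types)) {
    mu_t <- mu0
    mu_t[genes %in% markers[[t]]] <- mu_t[genes %in% markers[[t]]] * fold_change
    cols <- which(type_of_cell == t)
    counts[, cols] <- stats::rnbinom(n_genes * length(cols),
                                     mu = mu_t, size = 1 / dispersion)
  }

  # covariates mildly informative of expression level
  z <- as.numeric(scale(log(mu0)))
  tx_length <- pmax(200, round(exp(log(2500) + 0.35 * z +
                                     stats::rnorm(n_genes, 0, 0.6))))
  gc <- pmin(0.75, pmax(0.25, 0.45 + 0.03 * z + stats::rnorm(n_genes, 0, 0.05)))
  annot <- simulate_gene_coordinates(n_genes, seed = seed + 1L,
                                     gene_names = genes)
  annot$tx_length <- tx_length
  annot$end <- annot$start + tx_length
  annot$gc <- gc

  list(counts = counts,
       cell_meta = data.frame(cell_id = colnames(counts),
                              cell_type = type_of_cell,
                              stringsAsFactors = FALSE),
       gene_annot = annot,
       truth = list(markers = markers, fold_change = fold_change,
                    dispersion = dispersion, baseline_mu = mu0))
}

#' Simulate multi-tissue expression with planted correlated gene blocks
#'
#' Each planted block follows a single-factor model: for a gene in a block of
#' strength `s`, expression is `sqrt(s) * f + noise_sd * sqrt(1 - s) * e`
#' with a per-(tissue, sample) latent factor `f`, giving expected pairwise
#' within-block correlation `s` when `noise_sd = 1`. A block may be declared
#' tissue-specific: its loadings are zero outside its home tissue, emulating
#' a co-expression signature found in one brain region only. Background
#' genes are pure noise.
#'
#' @param n_genes Number of genes per tissue matrix.
#' @param tissues Character vector of tissue names.
#' @param n_samples Samples per tissue.
#' @param blocks List of blocks, each `list(size=, strength=, tissue=)` where
#'   `tissue` is `"all"` (default) or one tissue name. Blocks claim leading
#'   gene indices in order.
#' @param noise_sd Idiosyncratic noise scale (> 0).
#' @param seed Integer seed.
#' @param gene_names Optional symbols (default `G00001`, ...).
#' @return List: `expr` (named list of genes x samples matrices), `truth`
#'   (`block` gene -> block id or 0, `strength`, `tissue` per block).
#' @export
simulate_tissue_expression <- function(n_genes, tissues, n_samples, blocks,
                                       noise_sd = 1, seed = 1,
                                       gene_names = NULL) {
  if (noise_sd <= 0) dn_stop("noise_sd must be > 0")
  sizes <- vapply(blocks, function(b) as.integer(b$size), 1L)
  if (any(sizes < 3L)) dn_stop("block sizes must be >= 3")
  if (sum(sizes) > n_genes) dn_stop("block sizes sum exceeds n_genes")
  strengths <- vapply(blocks, function(b) as.numeric(b$strength), 1)
  if (any(strengths <= 0 | strengths >= 1))
    dn_stop("block strengths must lie in (0,1)")
  home <- vapply(blocks, function(b) as.character(b$tissue %||% "all"), "")
  bad <- setdiff(setdiff(home, "all"), tissues)
  if (length(bad)) dn_stop("unknown block tissue: ", paste(bad, collapse = ", "))

  set.seed(seed)
  if (is.null(gene_names)) gene_names <- sprintf("G%05d", seq_len(n_genes))
  block_of <- integer(n_genes)
  at <- 1L
  for (i in seq_along(blocks)) {
    block_of[at:(at + sizes[i] - 1L)] <- i
    at <- at + sizes[i]
  }
  expr <- list()
  for (ts in tissues) {
    x <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                n_genes, n_samples,
                dimnames = list(gene_names,
                                sprintf("%s_S%03d", ts, seq_len(n_samples))))
    for (i in seq_along(blocks)) {
      if (home[i] != "all" && home[i] != ts) next
      f <- stats::rnorm(n_samples)
      rows <- which(block_of == i)
      lam <- sqrt(strengths[i])
      sig <- noise_sd * sqrt(1 - strengths[i])
      x[rows, ] <- lam * matrix(f, length(rows), n_samples, byrow = TRUE) +
        sig * matrix(stats::rnorm(length(rows) * n_samples), length(rows))
    }
    expr[[ts]] <- x
  }
  truth_block <- stats::setNames(block_of, gene_names)
  list(expr = expr,
       truth = list(block = truth_block, strength = strengths, tissue = home))
}

#' Simulate an LD reference panel with block-correlated genotypes
#'
#' SNPs are laid out in consecutive non-overlapping blocks. Haplotypes copy a
#' per-block core haplotype with probability `sqrt(within_block_rho)` (and
#' are redrawn from the block allele frequency otherwise), so the expected
#' pairwise Pearson correlation of dosages within a block is exactly
#' `within_block_rho`; SNPs in different blocks are independent. Dosages are
#' 0/1/2. Monomorphic SNPs are redrawn (deterministically under the seed).
#'
#' @param n_snps Number of SNPs.
#' @param n_individuals Panel size.
#' @param block_size SNPs per LD block.
#' @param within_block_rho Target within-block dosage correlation in [0, 1).
#' @param maf_range Block allele-frequency range, a sub-interval of (0, 0.5].
#' @param chrom_length Chromosome length in bp (positions strictly increase).
#' @param seed Integer seed.
#' @return List: `dosage` (SNP x individual matrix), `map` (data frame
#'   `snp`, `chrom`, `pos`, `maf` with empirical folded MAF), `block`
#'   (integer block id per SNP).
#' @export
simulate_ld_reference <- function(n_snps, n_individuals, block_size = 20,
                                  within_block_rho = 0.6,
                                  maf_range = c(0.05, 0.5),
                                  chrom_length = 1e8, seed = 1) {
  if (within_block_rho < 0 || within_block_rho >= 1)
    dn_stop("within_block_rho must lie in [0,1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    dn_stop("maf_range must lie within (0, 0.5]")
  set.seed(seed)
  a <- sqrt(within_block_rho)
  n_blocks <- ceiling(n_snps / block_size)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_snps)]
  pos <- sort(sample.int(chrom_length, n_snps))
  snps <- sprintf("rs%06d", seq_len(n_snps))
  dosage <- matrix(0L, n_snps, n_individuals,
                   dimnames = list(snps, sprintf("I%04d", seq_len(n_individuals))))
  draw_hap <- function(core, p) {
    copy <- stats::runif(length(core)) < a
    ifelse(copy, core, stats::runif(length(core)) < p) * 1L
  }
  for (b in seq_len(n_blocks)) {
    p <- stats::runif(1, maf_range[1], maf_range[2])
    core1 <- (stats::runif(n_individuals) < p) * 1L
    core2 <- (stats::runif(n_individuals) < p) * 1L
    rows <- which(block_of == b)
    for (j in rows) {
      d <- draw_hap(core1, p) + draw_hap(core2, p)
      while (length(unique(d)) == 1L)  # redraw monomorphic SNPs
        d <- draw_hap(core1, p) + draw_hap(core2, p)
      dosage[j, ] <- d
    }
  }
  freq <- rowMeans(dosage) / 2
  maf <- pmin(freq, 1 - freq)
  list(dosage = dosage,
       map = data.frame(snp = snps, chrom = "1", pos = pos, maf = maf,
                        stringsAsFactors = FALSE),
       block = block_of)
}

#' Simulate GWAS summary statistics from the stratified LD-score model
#'
#' Draws per-SNP z-scores independently from
#' `Normal(0, sqrt(1 + N * sum_C tau_C * l(j, C)))`, the expectation model of
#' stratified LD-score regression, with LD scores `l(j, C)` computed from the
#' supplied reference panel by [compute_ld_scores()]. This is the exact
#' generative inverse of the estimator in [stratified_regression()], so
#' planted `tau` values are recoverable.
#'
#' @param ld_ref Panel from [simulate_ld_reference()].
#' @param annot SNP x category binary matrix (must include all categories in
#'   `tau`; typically contains a `base` column of ones).
#' @param tau Named numeric vector of per-SNP heritability coefficients, one
#'   per annotation category.
#' @param N GWAS sample size (scalar).
#' @param seed Integer seed.
#' @param window_bp LD-score window passed to [compute_ld_scores()].
#' @param ld_scores Optional precomputed LD-score matrix (SNP x category)
#'   to avoid recomputation across simulation replicates.
#' @return List: `sumstats` (data frame `snp`, `a1`, `a2`, `z`, `n`),
#'   `ld_scores` (the matrix used).
#' @export
simulate_sumstats <- function(ld_ref, annot, tau, N, seed = 1,
                              window_bp = 1e6, ld_scores = NULL) {
  if (is.null(names(tau)) || !all(names(tau) %in% colnames(annot)))
    dn_stop("tau must be named by annotation categories present in annot")
  if (is.null(ld_scores))
    ld_scores <- compute_ld_scores(ld_ref, annot, window_bp = window_bp)
  v <- 1 + N * as.numeric(ld_scores[, names(tau), drop = FALSE] %*% tau)
  if (any(v <= 0))
    dn_stop("negative chi-square variance at SNP ",
            ld_ref$map$snp[which(v <= 0)[1]])
  set.seed(seed)
  z <- stats::rnorm(length(v), 0, sqrt(v))
  list(sumstats = data.frame(snp = ld_ref$map$snp, a1 = "A", a2 = "G",
                             z = z, n = N, stringsAsFactors = FALSE),
       ld_scores = ld_scores)
}

#' Write summary statistics in LDSC-style whitespace-delimited format
#' @param sumstats Data frame from [simulate_sumstats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$snp, A1 = sumstats$a1, A2 = sumstats$a2,
                    Z = sumstats$z, N = sumstats$n)
  utils::write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}
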