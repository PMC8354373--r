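# Independent oracles used across the suite. These deliberately re-derive
# quantities by direct enumeration / naive loops, never by calling the
# package code paths they check.

# topological overlap by the definitional triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
    tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# hypergeometric upper tail by explicit binomial-coefficient sums:
# draw set_size genes from a background of bg_size containing target_size
# "successes"; P(overlap >= ov)
oracle_hyper_tail <- function(ov, set_size, target_size, bg_size) {
  js <- ov:min(set_size, target_size)
  sum(choose(target_size, js) * choose(bg_size - target_size, set_size - js)) /
    choose(bg_size, set_size)
}

# Spearman rho via the rank formula with mid-ranks
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# brute-force LD scores: double loop over SNP pairs with the unbiased r^2
# adjustment and a physical window
oracle_ld_scores <- function(dosage, map, annot, window_bp) {
  n_snp <- nrow(dosage)
  n <- ncol(dosage)
  out <- matrix(0, n_snp, ncol(annot), dimnames = list(map$snp, colnames(annot)))
  for (j in seq_len(n_snp)) for (k in seq_len(n_snp)) {
    if (map$chrom[j] != map$chrom[k]) next
    if (abs(map$pos[j] - map$pos[k]) > window_bp) next
    r2 <- stats::cor(dosage[j, ], dosage[k, ])^2
    r2a <- r2 - (1 - r2) / (n - 2)
    out[j, ] <- out[j, ] + r2a * annot[k, ]
  }
  out
}

# planted 3-block tissue dataset shared by network tests
make_planted_blocks <- function(n_genes = 1000, strength = 0.8,
                                n_samples = 150, seed = 4,
                                sizes = c(60, 40, 30)) {
  blocks <- lapply(sizes, function(s) list(size = s, strength = strength))
  simulate_tissue_expression(n_genes, "t", n_samples, blocks, seed = seed)
}

# small specificity fixture with hand-computable values
make_toy_counts <- function() {
  m <- matrix(c(
    4, 4, 0, 0, 0, 0,   # gene only in type A
    2, 2, 2, 2, 2, 2,   # equal everywhere
    0, 0, 1, 3, 4, 4),  # mixed
    nrow = 3, byrow = TRUE,
    dimnames = list(c("GA", "GB", "GC"), paste0("c", 1:6)))
  list(counts = m, types = rep(c("A", "B", "C"), each = 2))
}
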