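# density: mean off-diagonal signed adjacency among a gene set
module_density <- function(expr, genes, beta) {
  a <- signed_adjacency(expr[genes, , drop = FALSE], beta)
  n <- nrow(a)
  (sum(a) - n) / (n * (n - 1))
}

# intramodular connectivity vector (within-set, excluding self)
intra_connectivity <- function(expr, genes, beta) {
  a <- signed_adjacency(expr[genes, , drop = FALSE], beta)
  rowSums(a) - 1
}

#' Module preservation Z statistics between tissues
#'
#' For each module defined in a reference tissue, computes in a test tissue:
#' a density statistic (mean within-module signed adjacency) and a
#' connectivity statistic (Pearson correlation of the intramodular
#' connectivity vectors between reference and test tissue). Each observed
#' statistic is standardized against `n_permutations` random gene sets of
#' the same size drawn uniformly from the shared gene universe (module
#' members are not excluded from the draws), giving Zdensity and
#' Zconnectivity; `Zsummary` is their mean. Modules with fewer than 3 genes
#' in the shared universe are skipped with a warning.
#'
#' @param ref_expr,test_expr Genes x samples matrices (gene universes are
#'   intersected; the intersection size is logged).
#' @param labels Module labels defined in the reference tissue.
#' @param beta Soft power for the signed adjacency.
#' @param n_permutations Null gene sets per module (default 200; 50 in test
#'   configurations).
#' @param seed Integer seed.
#' @return Data frame, one row per module: `module`, `size`, `density`,
#'   `connectivity`, `z_density`, `z_connectivity`, `z_summary`,
#'   `category` (from [classify_preservation()]), `degenerate` (TRUE when a
#'   permutation sd was 0 and the Z was set to NA).
#' @export
preservation_statistics <- function(ref_expr, test_expr, labels, beta,
                                    n_permutations = 200, seed = 1) {
  shared <- intersect(rownames(ref_expr), rownames(test_expr))
  dn_log("preserve", sprintf("shared gene universe: %d genes", length(shared)))
  labels <- labels[names(labels) %in% shared]
  mods <- setdiff(unique(labels), "grey")
  set.seed(seed)
  rows <- list()
  for (mod in mods) {
    genes <- names(labels)[labels == mod]
    if (length(genes) < 3L) {
      warning("module '", mod, "' smaller than 3 in shared universe; skipped",
              call. = FALSE)
      next
    }
    obs_d <- module_density(test_expr, genes, beta)
    obs_c <- stats::cor(intra_connectivity(ref_expr, genes, beta),
                        intra_connectivity(test_expr, genes, beta))
    null_d <- numeric(n_permutations)
    null_c <- numeric(n_permutations)
    for (i in seq_len(n_permutations)) {
      rs <- sample(shared, length(genes))
      null_d[i] <- module_density(test_expr, rs, beta)
      null_c[i] <- stats::cor(intra_connectivity(ref_expr, rs, beta),
                              intra_connectivity(test_expr, rs, beta))
    }
    zd <- if (stats::sd(null_d) > 0) (obs_d - mean(null_d)) / stats::sd(null_d)
      else NA_real_
    zc <- if (stats::sd(null_c) > 0) (obs_c - mean(null_c)) / stats::sd(null_c)
      else NA_real_
    zs <- mean(c(zd, zc))
    rows[[length(rows) + 1L]] <- data.frame(
      module = mod, size = length(genes), density = obs_d,
      connectivity = obs_c, z_density = zd, z_connectivity = zc,
      z_summary = zs,
      category = if (is.finite(zs)) classify_preservation(zs) else NA_character_,
      degenerate = !is.finite(zs), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Classify a preservation Z-summary value
#'
#' Z-summary > 10: strong evidence of preservation; 2 < Z <= 10: weak to
#' moderate; Z <= 2: none. Boundary values fall in the lower category.
#'
#' @param z Finite numeric Z-summary.
#' @return `"strong"`, `"weak-moderate"`, or `"none"`.
#' @export
classify_preservation <- function(z) {
  if (length(z) != 1L || !is.finite(z)) dn_stop("z must be a finite scalar")
  if (z > 10) "strong" else if (z > 2) "weak-moderate" else "none"
}

#' Median preservation across test tissues
#'
#' @param results Data frame stacking [preservation_statistics()] outputs
#'   over test tissues (must contain columns `module`, `z_summary`).
#' @return Data frame: `module`, `n_tissues`, `median_z`, `category` of the
#'   median.
#' @export
summarize_preservation <- function(results) {
  mods <- unique(results$module)
  out <- lapply(mods, function(mod) {
    z <- results$z_summary[results$module == mod]
    z <- z[is.finite(z)]
    med <- stats::median(z)
    data.frame(module = mod, n_tissues = length(z), median_z = med,
               category = classify_preservation(med),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
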