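# Fixed color-name sequence for module labels, assigned by decreasing module
# size; "grey" is reserved for unassigned genes.
module_color_sequence <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
  "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
  "brown4", "bisque4", "darkslateblue", "plum2", "thistle2")

#' Signed co-expression adjacency
#'
#' `a(i,j) = ((1 + r(i,j)) / 2)^beta` with `r` the Pearson correlation of
#' gene profiles across samples, so perfect anticorrelation maps to 0 and
#' perfect correlation to 1 ("signed" network).
#'
#' @param expr Genes x samples numeric matrix.
#' @param beta Soft-thresholding power (integer >= 1).
#' @return Symmetric genes x genes adjacency with unit diagonal.
#' @export
signed_adjacency <- function(expr, beta) {
  if (beta < 1) dn_stop("beta must be >= 1")
  if (ncol(expr) < 3L) dn_stop("need at least 3 samples")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0))
    dn_stop("zero-variance gene(s): ",
            paste(utils::head(rownames(expr)[v == 0], 10), collapse = ", "))
  r <- stats::cor(t(expr))
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM(i,j) = (sum_u a(i,u) a(u,j) + a(i,j)) / (min(k_i, k_j) + 1 - a(i,j))`
#' where the sum excludes `u = i, j` and `k_i` is the connectivity of node i
#' excluding itself. Shared-neighbor structure smooths the adjacency;
#' `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency Symmetric matrix in [0,1] with unit diagonal.
#' @return Symmetric TOM matrix with unit diagonal, entries in [0,1].
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    dn_stop("adjacency must be symmetric")
  a <- adjacency
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  # sum over shared neighbors u != i,j: (A^2)_ij - a_ii a_ij - a_ij a_jj
  num <- a %*% a - 2 * a * matrix(diag(a), n, n)  # uses unit diagonal
  num <- num + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  (tom + t(tom)) / 2
}

#' Scale-free soft-power selection
#'
#' For each candidate power, computes the scale-free topology fit: the
#' signed R-squared of the regression of log10 frequency on log10 mean
#' connectivity over `n_bins` connectivity bins (negative when the slope is
#' positive). Returns the smallest power reaching `target_fit`, or the power
#' maximizing the fit (with a warning) if none does.
#'
#' @param expr Genes x samples matrix (>= 10 genes).
#' @param candidates Candidate powers (>= 2 values).
#' @param target_fit Target signed R-squared (default 0.8).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List: `beta`, `fit_table` (data frame `beta`, `fit_r2`,
#'   `mean_connectivity`).
#' @export
pick_soft_power <- function(expr, candidates = c(1:10, seq(12, 20, 2)),
                            target_fit = 0.8, n_bins = 10) {
  if (nrow(expr) < 10L) dn_stop("need at least 10 genes")
  if (length(candidates) < 2L) dn_stop("need at least 2 candidate powers")
  candidates <- sort(unique(candidates))
  r <- stats::cor(t(expr))
  base <- (1 + r) / 2
  diag(base) <- NA
  fit1 <- function(beta) {
    a <- base^beta
    k <- rowSums(a, na.rm = TRUE)
    br <- seq(min(k), max(k), length.out = n_bins + 1)  # equal-width bins
    if (length(unique(br)) < 2L) return(c(NA_real_, mean(k)))
    cutk <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- as.numeric(table(cutk))
    meank <- tapply(k, cutk, mean)
    ok <- freq > 0 & meank > 0
    if (sum(ok) < 3L) return(c(NA_real_, mean(k)))
    rho <- stats::cor(log10(meank[ok]), log10(freq[ok]))
    c(-sign(rho) * rho^2, mean(k))  # signed R^2: negative slope is scale-free

  }
  stats_tab <- t(vapply(candidates, fit1, numeric(2)))
  tab <- data.frame(beta = candidates, fit_r2 = stats_tab[, 1],
                    mean_connectivity = stats_tab[, 2])
  hit <- which(!is.na(tab$fit_r2) & tab$fit_r2 >= target_fit)
  if (length(hit)) {
    beta <- candidates[hit[1]]
  } else {
    beta <- candidates[which.max(tab$fit_r2)]
    warning("no candidate power reached target fit ", target_fit,
            "; using the best-fitting power ", beta, call. = FALSE)
  }
  list(beta = beta, fit_table = tab)
}

#' Initial module detection by hierarchical clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering of the `1 - TOM` dissimilarity,
#' cut at a static height. Clusters smaller than `min_size` are merged into
#' "grey" (unassigned); surviving modules are labeled with a fixed color
#' sequence by decreasing size, making labels deterministic.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param cut_height Static tree-cut height in (0, 1] (default 0.92).
#' @param min_size Minimum module size (default 30, >= 3).
#' @return Named character vector of module labels per gene.
#' @export
cluster_modules <- function(tom, cut_height = 0.92, min_size = 30) {
  if (min_size < 3L) dn_stop("min_size must be >= 3")
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  relabel_by_size(raw, min_size, rownames(tom))
}

# size-ranked color relabeling; clusters below min_size become grey
relabel_by_size <- function(raw, min_size, gene_names) {
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  ord <- keep[order(-sizes[keep], as.numeric(keep))]
  if (length(ord) > length(module_color_sequence))
    dn_stop("more modules than available color labels")
  labels <- rep("grey", length(raw))
  for (i in seq_along(ord))
    labels[raw == ord[i]] <- module_color_sequence[i]
  stats::setNames(labels, gene_names)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' per-gene standardized (z-scored) expression of its members across
#' samples, scaled to unit norm and sign-anchored so that its mean
#' correlation with member genes is positive.
#'
#' @param expr Genes x samples matrix.
#' @param labels Module labels per gene ("grey" excluded).
#' @return Samples x modules matrix of eigengenes.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(match(mods, module_color_sequence))]
  if (length(mods) == 0L) dn_stop("no non-grey modules")
  me <- matrix(0, ncol(expr), length(mods),
               dimnames = list(colnames(expr), mods))
  for (mod in mods) {
    genes <- names(labels)[labels == mod]
    if (length(genes) < 2L) dn_stop("module '", mod, "' has fewer than 2 genes")
    x <- expr[genes, , drop = FALSE]
    v <- apply(x, 1L, stats::var)
    if (any(v == 0)) dn_stop("constant gene in module '", mod, "'")
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(t(xs), e)) < 0) e <- -e
    me[, mod] <- e
  }
  me
}

#' Module membership (kME)
#'
#' `kME(g, m)` is the Pearson correlation of gene g's expression profile
#' with module m's eigengene, computed for every gene-module pair (grey
#' genes included, so they can re-enter modules via the kME filter).
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @return Genes x modules matrix of correlations in [-1, 1].
#' @export
module_membership <- function(expr, eigengenes) {
  stats::cor(t(expr), eigengenes)
}

#' k-means-style refinement of module assignments
#'
#' Iteratively recomputes module eigengenes (the "centroids") and reassigns
#' every non-grey gene to the module of its highest kME, stopping early when
#' no gene moves or after `max_iter` iterations. Modules falling below
#' `min_size` dissolve into grey. Final eigengenes and kME are recomputed on
#' the refined labels.
#'
#' @param expr Genes x samples matrix.
#' @param labels Initial labels from [cluster_modules()].
#' @param max_iter Maximum iterations (default 30).
#' @param min_size Minimum module size (default 30).
#' @return List of class `module_assignment`: `labels`, `eigengenes`, `kme`,
#'   `n_iter`, `moved` (genes moved per iteration).
#' @export
kmeans_refine <- function(expr, labels, max_iter = 30, min_size = 30) {
  labels <- labels[rownames(expr)]
  moved <- integer(0)
  for (it in seq_len(max_iter)) {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) == 0L) break
    me <- module_eigengenes(expr, labels)
    kme <- module_membership(expr, me)
    assignable <- names(labels)[labels != "grey"]
    best <- colnames(kme)[max.col(kme[assignable, , drop = FALSE],
                                  ties.method = "first")]
    n_moved <- sum(best != labels[assignable])
    labels[assignable] <- best
    # dissolve undersized modules
    sizes <- table(labels[labels != "grey"])
    small <- names(sizes)[sizes < min_size]
    if (length(small)) labels[labels %in% small] <- "grey"
    moved <- c(moved, n_moved)
    if (n_moved == 0L && length(small) == 0L) break
  }
  me <- module_eigengenes(expr, labels)
  kme <- module_membership(expr, me)
  structure(list(labels = labels, eigengenes = me, kme = kme,
                 n_iter = length(moved), moved = moved),
            class = "module_assignment")
}

#' Build a signed co-expression network end-to-end
#'
#' Convenience wrapper: signed adjacency, TOM, hierarchical module
#' detection, k-means refinement, eigengenes and kME.
#'
#' @param expr Genes x samples matrix.
#' @param beta Soft power; `NULL` to select via [pick_soft_power()].
#' @param cut_height,min_size,kmeans_iters Network parameters (defaults
#'   0.92, 30, 30).
#' @param target_fit Scale-free fit target when `beta = NULL`.
#' @return A `module_assignment` (see [kmeans_refine()]) with extra elements
#'   `beta`, `initial_labels`, `params`.
#' @export
build_network <- function(expr, beta = NULL, cut_height = 0.92,
                          min_size = 30, kmeans_iters = 30,
                          target_fit = 0.8) {
  if (is.null(beta)) beta <- pick_soft_power(expr, target_fit = target_fit)$beta
  a <- signed_adjacency(expr, beta)
  tom <- topological_overlap(a)
  init <- cluster_modules(tom, cut_height = cut_height, min_size = min_size)
  out <- kmeans_refine(expr, init, max_iter = kmeans_iters,
                       min_size = min_size)
  out$beta <- beta
  out$initial_labels <- init
  out$params <- list(cut_height = cut_height, min_size = min_size,
                     kmeans_iters = kmeans_iters)
  out
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- sort(table(x$labels[x$labels != "grey"]), decreasing = TRUE)
  cat(sprintf("<module_assignment> %d genes, %d modules (+%d grey)\n",
              length(x$labels), length(sizes), sum(x$labels == "grey")))
  print(sizes)
  invisible(x)
}
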