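#' LD scores per annotation category
#'
#' The LD score of SNP j with respect to category C is
#' `l(j,C) = sum_{k in C, |pos_k - pos_j| <= window} r2_adj(j,k)` with the
#' unbiased adjustment `r2_adj = r2 - (1 - r2)/(n - 2)` (n = panel
#' individuals), which centers null squared correlations at zero. The self
#' term (j in C) contributes exactly 1. Correlations are computed within a
#' physical window, chunked through BLAS matrix products.
#'
#' @param ld_ref Panel from [simulate_ld_reference()] (or any list with
#'   `dosage` SNP x individual and `map` with `snp`, `chrom`, `pos`).
#' @param annot SNP x category binary matrix, rows aligned with the map.
#' @param window_bp Window half-width in bp (default 1 Mb, a
#'   physical-distance stand-in for the conventional 1 cM).
#' @param chunk Chunk size for the blocked computation.
#' @return SNP x category matrix of LD scores.
#' @export
compute_ld_scores <- function(ld_ref, annot, window_bp = 1e6, chunk = 512L) {
  X <- ld_ref$dosage
  map <- ld_ref$map
  n_ind <- ncol(X)
  if (n_ind < 10L) dn_stop("need at least 10 panel individuals")
  annot <- as.matrix(annot)
  if (nrow(annot) != nrow(X)) dn_stop("annotation rows must match panel SNPs")
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n_ind - 1))
  if (any(sdv == 0))
    dn_stop("monomorphic SNP(s): ",
            paste(utils::head(map$snp[sdv == 0], 10), collapse = ", "))
  Z <- (X - mu) / (sdv * sqrt(n_ind - 1))  # Z %*% t(Z) = correlation matrix
  ell <- matrix(0, nrow(X), ncol(annot),
                dimnames = list(map$snp, colnames(annot)))
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    pos <- map$pos[rows]
    starts <- seq(1L, length(rows), by = chunk)
    for (s in starts) {
      cr <- rows[s:min(s + chunk - 1L, length(rows))]
      pr <- map$pos[cr]
      nb <- rows[pos >= min(pr) - window_bp & pos <= max(pr) + window_bp]
      R <- Z[cr, , drop = FALSE] %*% t(Z[nb, , drop = FALSE])
      r2 <- R^2
      r2 <- r2 - (1 - r2) / (n_ind - 2)
      within <- abs(outer(pr, map$pos[nb], "-")) <= window_bp
      r2[!within] <- 0
      ell[cr, ] <- ell[cr, ] + r2 %*% annot[nb, , drop = FALSE]
    }
  }
  ell
}

#' Binary SNP annotation from a kME-filtered gene set
#'
#' Retains the genes whose (signed) module membership is at least
#' `kme_threshold` (inclusive), extends each gene's coordinates by
#' `flank_bp` upstream and downstream (clipped at zero; 0-based half-open
#' arithmetic), and marks every SNP with MAF strictly above `maf_min` lying
#' inside any extended interval on the same chromosome.
#'
#' @param genes Character vector of module gene symbols.
#' @param kme Named numeric vector of module membership for `genes` (a gene
#'   missing from `kme` is treated as failing the filter).
#' @param coords Gene annotation table (`gene`, `chrom`, `start`, `end`);
#'   genes without coordinates are dropped and logged.
#' @param snp_map Data frame `snp`, `chrom`, `pos`, `maf`.
#' @param kme_threshold Minimum kME (default 0.5).
#' @param flank_bp Flank in bp (default 100,000).
#' @param maf_min MAF lower bound, exclusive (default 0.05).
#' @return Named integer 0/1 vector over the SNPs of `snp_map`. All-zero
#'   (with a warning) when no gene survives the filters.
#' @export
build_gene_annotation <- function(genes, kme, coords, snp_map,
                                  kme_threshold = 0.5, flank_bp = 1e5,
                                  maf_min = 0.05) {
  genes <- normalize_symbols(genes)
  keep <- genes[!is.na(kme[genes]) & kme[genes] >= kme_threshold]
  idx <- match(keep, normalize_symbols(coords$gene))
  if (anyNA(idx)) {
    dn_log("sldsc", sprintf("dropped %d gene(s) without coordinates",
                            sum(is.na(idx))))
    keep <- keep[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  out <- stats::setNames(integer(nrow(snp_map)), snp_map$snp)
  if (length(keep) == 0L) {
    warning("no genes retained by the kME filter; annotation is all zero",
            call. = FALSE)
    return(out)
  }
  maf_ok <- snp_map$maf > maf_min
  for (i in seq_along(idx)) {
    lo <- max(0, coords$start[idx[i]] - flank_bp)
    hi <- coords$end[idx[i]] + flank_bp
    hit <- maf_ok & snp_map$chrom == coords$chrom[idx[i]] &
      snp_map$pos >= lo & snp_map$pos < hi
    out[hit] <- 1L
  }
  out
}

#' Exclude SNPs falling in genomic regions
#'
#' Removes from the regression the SNPs lying inside any of the given
#' half-open, 0-based regions (e.g. an MHC-style long-range LD region).
#' Excluded SNPs may still act as LD partners in [compute_ld_scores()]; the
#' filter applies only to the regression rows.
#'
#' @param snp_map Data frame `snp`, `chrom`, `pos`.
#' @param regions Data frame `chrom`, `start`, `end` (may have zero rows).
#' @return Integer indices of the retained SNPs.
#' @export
exclude_region <- function(snp_map, regions) {
  drop <- rep(FALSE, nrow(snp_map))
  if (!is.null(regions) && nrow(regions) > 0L) {
    for (i in seq_len(nrow(regions))) {
      drop <- drop | (snp_map$chrom == regions$chrom[i] &
                        snp_map$pos >= regions$start[i] &
                        snp_map$pos < regions$end[i])
    }
  }
  if (all(drop)) dn_stop("no SNPs remain after region exclusion")
  which(!drop)
}

#' Stratified LD-score regression with block-jackknife inference
#'
#' Weighted least squares of per-SNP chi-square statistics on
#' `N * l(j, C)` for the baseline categories plus one target category, with
#' an intercept. Weights are `1 / max(1, l_base)^2`, a heteroskedasticity
#' proxy; chi-square values are not truncated. Standard errors come from a
#' delete-one block jackknife over contiguous equal-count SNP blocks in map
#' order. The coefficient p-value is one-tailed (`1 - Phi(z)`), testing for
#' a positive per-SNP heritability contribution.
#'
#' @param sumstats Data frame `snp`, `z`, `n` (as from [simulate_sumstats()]).
#' @param ld_scores SNP x category LD-score matrix containing a `base`
#'   column and all tested categories, rows in map order.
#' @param baseline Character vector of baseline category names (must include
#'   `"base"`).
#' @param target Target category name (tested jointly with the baseline).
#' @param n_blocks Jackknife blocks (default 200, >= 2).
#' @param snp_keep Optional integer indices restricting the regression (from
#'   [exclude_region()]).
#' @return List of class `sldsc_fit`: `coefficients` (data frame `category`,
#'   `tau`, `se`, `z`, `p`), `intercept`, `n_snps`, `n_blocks`.
#' @export
stratified_regression <- function(sumstats, ld_scores, baseline, target,
                                  n_blocks = 200, snp_keep = NULL) {
  if (n_blocks < 2L) dn_stop("n_blocks must be >= 2")
  cats <- c(baseline, target)
  if (anyDuplicated(cats))
    dn_stop("duplicated categories: ",
            paste(unique(cats[duplicated(cats)]), collapse = ", "))
  if (!all(cats %in% colnames(ld_scores)))
    dn_stop("missing LD-score columns: ",
            paste(setdiff(cats, colnames(ld_scores)), collapse = ", "))
  ix <- match(sumstats$snp, rownames(ld_scores))
  if (anyNA(ix)) dn_stop("sumstats SNPs missing from LD scores")
  # jackknife blocks are contiguous in map order, so sort to the LD-score
  # (map) order; estimates are then invariant to sumstats row order
  ord <- order(ix)
  sumstats <- sumstats[ord, , drop = FALSE]
  ix <- ix[ord]
  L <- ld_scores[ix, cats, drop = FALSE]
  base_l <- ld_scores[ix, "base"]
  keep <- if (is.null(snp_keep)) seq_along(ix) else which(ix %in% snp_keep)
  L <- L[keep, , drop = FALSE]
  base_l <- base_l[keep]
  y <- sumstats$z[keep]^2
  N <- sumstats$n[keep]
  X <- cbind(intercept = 1, L * N)
  if (qr(X)$rank < ncol(X)) {
    cc <- stats::cor(X[, -1, drop = FALSE])
    dup <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
    dn_stop("rank-deficient design; collinear columns: ",
            paste(unique(cats[c(dup)]), collapse = ", "))
  }
  w <- 1 / pmax(1, base_l)^2
  n <- nrow(X)
  block <- ceiling(seq_len(n) / n * n_blocks)
  p <- ncol(X)
  # per-block normal-equation pieces; delete-one = total - block
  XtWX_b <- array(0, c(p, p, n_blocks))
  XtWy_b <- matrix(0, p, n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- which(block == b)
    Xb <- X[rows, , drop = FALSE]
    wb <- w[rows]
    XtWX_b[, , b] <- crossprod(Xb * wb, Xb)
    XtWy_b[, b] <- crossprod(Xb * wb, y[rows])
  }
  XtWX <- apply(XtWX_b, c(1, 2), sum)
  XtWy <- rowSums(XtWy_b)
  beta_full <- solve(XtWX, XtWy)
  beta_jk <- matrix(0, p, n_blocks)
  for (b in seq_len(n_blocks))
    beta_jk[, b] <- solve(XtWX - XtWX_b[, , b], XtWy - XtWy_b[, b])
  jk_mean <- rowMeans(beta_jk)
  se <- sqrt((n_blocks - 1) / n_blocks *
               rowSums((beta_jk - jk_mean)^2))
  zsc <- beta_full / se
  coefs <- data.frame(category = cats,
                      tau = beta_full[-1], se = se[-1], z = zsc[-1],
                      p = stats::pnorm(zsc[-1], lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, intercept = beta_full[1],
                 intercept_se = se[1], n_snps = n, n_blocks = n_blocks),
            class = "sldsc_fit")
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat(sprintf("<sldsc_fit> %d SNPs, %d jackknife blocks, intercept %.3f\n",
              x$n_snps, x$n_blocks, x$intercept))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Heritability battery over module annotations and GWAS
#'
#' Runs one stratified regression per (module annotation, GWAS) pair, each
#' adding the module category to the baseline model, and flags rows by the
#' Bonferroni threshold `alpha / (n_modules * n_gwas)` and by nominal
#' significance (p < 0.05 without passing Bonferroni).
#'
#' @param modules Named list of binary SNP annotation vectors (one per
#'   module, e.g. from [build_gene_annotation()]).
#' @param gwas Named list of sumstats data frames.
#' @param ld_ref LD reference panel.
#' @param baseline_annot SNP x category matrix of baseline annotations
#'   (must include a `base` column of ones).
#' @param window_bp,n_blocks,snp_keep Passed to the LD-score and regression
#'   steps.
#' @param alpha Family-wise level (default 0.05).
#' @param baseline_scores Optional precomputed LD scores for
#'   `baseline_annot`.
#' @return Data frame: `module`, `gwas`, `tau`, `se`, `z`, `p`,
#'   `bonferroni_significant`, `nominal`; attribute `threshold`.
#' @export
run_heritability_battery <- function(modules, gwas, ld_ref, baseline_annot,
                                     window_bp = 1e6, n_blocks = 200,
                                     snp_keep = NULL, alpha = 0.05,
                                     baseline_scores = NULL) {
  if (length(modules) < 1L || length(gwas) < 1L)
    dn_stop("need at least one module and one GWAS")
  if (!"base" %in% colnames(baseline_annot))
    dn_stop("baseline_annot must contain a 'base' column")
  if (is.null(baseline_scores))
    baseline_scores <- compute_ld_scores(ld_ref, baseline_annot, window_bp)
  thr <- bonferroni_threshold(length(modules), length(gwas), alpha)
  rows <- list()
  for (mod in names(modules)) {
    mscore <- compute_ld_scores(
      ld_ref, matrix(modules[[mod]], ncol = 1,
                     dimnames = list(ld_ref$map$snp, mod)), window_bp)
    scores <- cbind(baseline_scores, mscore)
    for (gw in names(gwas)) {
      fit <- stratified_regression(gwas[[gw]], scores,
                                   baseline = colnames(baseline_annot),
                                   target = mod, n_blocks = n_blocks,
                                   snp_keep = snp_keep)
      co <- fit$coefficients[fit$coefficients$category == mod, ]
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, gwas = gw, tau = co$tau, se = co$se, z = co$z,
        p = co$p, bonferroni_significant = co$p < thr,
        nominal = co$p < 0.05 & co$p >= thr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
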