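#' Joint transcript-length x GC covariate bins
#'
#' Bins the background genes by the joint quantile bin of transcript length
#' and GC fraction (quantile boundaries computed on the background only).
#' Bootstrap replicates drawn per bin then have covariate composition
#' comparable to the target list, controlling transcript-length and GC
#' biases of the enrichment test.
#'
#' @param annot Gene annotation table with columns `gene`, `tx_length`, `gc`.
#' @param background Character vector of background gene symbols.
#' @param n_quantiles Quantile bins per covariate (default 10: decile
#'   matching, 10 x 10 joint bins).
#' @return List of class `covariate_bins`: `bins` (named integer-coded bin id
#'   per background gene), `breaks_length`, `breaks_gc`, `n_quantiles`.
#' @export
match_covariate_bins <- function(annot, background, n_quantiles = 10) {
  background <- unique(normalize_symbols(background))
  if (n_quantiles < 1) dn_stop("n_quantiles must be >= 1")
  idx <- match(background, normalize_symbols(annot$gene))
  if (anyNA(idx))
    dn_stop("genes missing annotation: ",
            paste(utils::head(background[is.na(idx)], 10), collapse = ", "))
  bin1d <- function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
                                                  n_quantiles + 1)))
    if (length(br) < 2L) return(rep(1L, length(x)))  # degenerate: one bin
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
  }
  bl <- bin1d(annot$tx_length[idx])
  bg <- bin1d(annot$gc[idx])
  joint <- as.integer(factor(paste(bl, bg)))
  structure(list(bins = stats::setNames(joint, background),
                 length_bin = stats::setNames(bl, background),
                 gc_bin = stats::setNames(bg, background),
                 n_quantiles = n_quantiles),
            class = "covariate_bins")
}

#' Expression-weighted cell-type enrichment by bootstrap
#'
#' Tests, per cell type, whether the summed specificity of a target gene list
#' exceeds that of random background lists of the same size. When covariate
#' bins are supplied, each replicate replaces every target gene with a random
#' background gene from the same transcript-length x GC bin (without
#' replacement within a replicate where the bin allows; exhausted bins fall
#' back to with-replacement with a logged warning). The p-value uses add-one
#' smoothing, `p = (1 + #(boot >= obs)) / (reps + 1)`, so it is never exactly
#' zero; `exact = TRUE` instead enumerates every possible target of the same
#' size from the background (small backgrounds only) and reports the exact
#' tail proportion without smoothing. The effect size is the number of
#' bootstrap standard deviations the observed score lies above the bootstrap
#' mean; negative values reflect depletion and are floored to 0 in the
#' `display` column. p-values are BH-adjusted across cell types.
#'
#' @param spec Specificity matrix from [compute_specificity()].
#' @param target A [gene_list()] or character vector of target genes.
#' @param background Character vector of background genes (default: all rows
#'   of `spec`). Target genes absent from background or `spec` are dropped
#'   and logged.
#' @param reps Bootstrap replicates (>= 1). 100,000 is the production
#'   default; tests use 2,000.
#' @param bins Optional [match_covariate_bins()] result, or `NULL` for
#'   unmatched sampling.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param exact If `TRUE`, enumerate all size-m subsets of the background
#'   instead of resampling (requires `choose(n, m) <= 2e5`; `bins` ignored).
#' @return Data frame with one row per cell type: `cell_type`, `observed`,
#'   `boot_mean`, `boot_sd`, `sd_from_mean`, `display`, `p`, `q`; attributes
#'   `reps`, `seed`, `n_target`.
#' @export
bootstrap_enrichment <- function(spec, target, background = NULL,
                                 reps = 1e5, bins = NULL, seed = 1,
                                 exact = FALSE) {
  tg <- if (inherits(target, "gene_list")) target$genes else
    normalize_symbols(target)
  rownames(spec) <- toupper(trimws(rownames(spec)))
  background <- unique(if (is.null(background)) rownames(spec) else
    normalize_symbols(background))
  background <- background[background %in% rownames(spec)]
  usable <- intersect(tg, background)
  dropped <- setdiff(tg, usable)
  if (length(dropped))
    dn_log("ewce", sprintf("dropped %d target gene(s) absent from spec/background",
                           length(dropped)))
  m <- length(usable)
  if (m == 0L) dn_stop("no usable target genes")
  if (!exact && reps < 1) dn_stop("reps must be >= 1")

  S <- spec[background, , drop = FALSE]
  n_ct <- ncol(S)
  observed <- colSums(S[usable, , drop = FALSE])

  if (exact) {
    n <- length(background)
    if (choose(n, m) > 2e5)
      dn_stop("exact mode infeasible: choose(n, m) too large")
    combs <- utils::combn(n, m)
    boot <- t(apply(combs, 2L, function(ix) colSums(S[ix, , drop = FALSE])))
    if (n_ct == 1L) boot <- matrix(boot, ncol = 1L)
    reps_eff <- ncol(combs)
    p <- colMeans(boot >= matrix(observed, reps_eff, n_ct, byrow = TRUE))
  } else {
    set.seed(seed)
    # sampled background indices: m rows (target slots) x reps columns
    draws <- matrix(0L, m, reps)
    if (is.null(bins)) {
      slot_bins <- rep(1L, m)
      bin_members <- list(seq_along(background))
    } else {
      bb <- bins$bins[background]
      if (anyNA(bb)) dn_stop("background genes missing from covariate bins")
      tb <- bins$bins[usable]
      slot_bins <- as.integer(factor(tb))
      bin_ids <- as.integer(levels(factor(tb)))
      bin_members <- lapply(bin_ids, function(b) which(bb == b))
    }
    for (b in seq_along(bin_members)) {
      slots <- which(slot_bins == b)
      members <- bin_members[[b]]
      t_b <- length(slots)
      if (t_b == 1L) {
        draws[slots, ] <- members[sample.int(length(members), reps,
                                             replace = TRUE)]
      } else if (length(members) >= t_b) {
        for (r in seq_len(reps))
          draws[slots, r] <- members[sample.int(length(members), t_b)]
      } else {
        dn_log("ewce", sprintf(
          "bin with %d member(s) exhausted by %d target gene(s); sampling with replacement",
          length(members), t_b))
        draws[slots, ] <- members[sample.int(length(members), t_b * reps,
                                             replace = TRUE)]
      }
    }
    boot <- matrix(0, reps, n_ct)
    for (slot in seq_len(m))
      boot <- boot + S[draws[slot, ], , drop = FALSE]
    p <- (1 + colSums(boot >= matrix(observed, reps, n_ct, byrow = TRUE))) /
      (reps + 1)
  }

  bm <- colMeans(boot)
  bs <- apply(boot, 2L, stats::sd)
  sdm <- ifelse(bs > 0, (observed - bm) / bs, 0)
  res <- data.frame(cell_type = colnames(S), observed = observed,
                    boot_mean = bm, boot_sd = bs, sd_from_mean = sdm,
                    display = pmax(0, sdm),
                    p = p, q = adjust_pvalues(p, "bh"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "reps") <- if (exact) NA_integer_ else reps
  attr(res, "seed") <- seed
  attr(res, "n_target") <- m
  res
}

#' Cell types significant after multiple-testing correction
#'
#' @param result Data frame from [bootstrap_enrichment()].
#' @param alpha Significance level on the BH-adjusted q-value (default 0.05).
#' @return Character vector of significant cell types.
#' @export
flag_significant <- function(result, alpha = 0.05) {
  result$cell_type[result$q < alpha]
}
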