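#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with enforced monotonicity, capped at 1) or
#' Bonferroni (`min(1, m p)`), delegating to [stats::p.adjust()] after
#' validating the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    dn_stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni")[method])
}

# one-tailed hypergeometric upper-tail p and odds ratio for an overlap
hyper_test <- function(overlap, set_size, target_size, background_size) {
  p <- stats::phyper(overlap - 1, target_size, background_size - target_size,
                     set_size, lower.tail = FALSE)
  a <- overlap
  b <- target_size - overlap
  c_ <- set_size - overlap
  d <- background_size - target_size - set_size + overlap
  or <- (a * d) / max(1e-12, (b * c_))
  list(p = min(1, p), odds_ratio = or)
}

#' Module over-representation of a target gene list
#'
#' For every non-grey module across one or more networks, computes the
#' one-tailed hypergeometric p-value of its overlap with the target list
#' given the background universe (default: the union of genes in the tested
#' networks). BH adjustment is applied jointly across all modules tested,
#' mirroring a single test family over all networks.
#'
#' @param assignments Named list of `module_assignment` objects (or plain
#'   named label vectors), one per network/tissue.
#' @param target A [gene_list()] or character vector. Target genes outside
#'   the background are dropped and logged.
#' @param background Optional character vector of background genes.
#' @return Data frame: `network`, `module`, `module_size`, `overlap`,
#'   `overlap_genes` (comma-separated), `target_size`, `background_size`,
#'   `odds_ratio`, `p`, `q`, sorted by p.
#' @export
module_list_enrichment <- function(assignments, target, background = NULL) {
  if (inherits(assignments, "module_assignment") ||
      (!is.list(assignments) && !is.null(names(assignments))))
    assignments <- list(network = assignments)
  label_sets <- lapply(assignments, function(a)
    if (inherits(a, "module_assignment")) a$labels else a)
  if (is.null(background))
    background <- unique(normalize_symbols(unlist(lapply(label_sets, names))))
  else background <- unique(normalize_symbols(background))
  tg <- if (inherits(target, "gene_list")) target$genes else
    normalize_symbols(target)
  usable <- intersect(tg, background)
  if (length(usable) < length(tg))
    dn_log("enrich", sprintf("dropped %d target gene(s) outside background",
                             length(tg) - length(usable)))
  if (length(usable) == 0L) dn_stop("empty target after background filtering")

  rows <- list()
  for (net in names(label_sets)) {
    labels <- label_sets[[net]]
    names(labels) <- normalize_symbols(names(labels))
    for (mod in setdiff(unique(labels), "grey")) {
      members <- intersect(names(labels)[labels == mod], background)
      ov <- intersect(members, usable)
      ht <- hyper_test(length(ov), length(members), length(usable),
                       length(background))
      rows[[length(rows) + 1L]] <- data.frame(
        network = net, module = mod, module_size = length(members),
        overlap = length(ov),
        overlap_genes = paste(sort(ov), collapse = ","),
        target_size = length(usable), background_size = length(background),
        odds_ratio = ht$odds_ratio, p = ht$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- adjust_pvalues(out$p, "bh")
  out[order(out$p), , drop = FALSE]
}

#' Over-representation analysis against a GMT collection
#'
#' Hypergeometric upper-tail test of a query gene list against each set in a
#' collection. Sets with fewer than `min_gene_count` members inside the
#' background are excluded before testing (and before BH adjustment), so
#' tiny terms do not enter the test family.
#'
#' @param query Character vector or [gene_list()] of query genes.
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param background Character vector of background genes.
#' @param min_gene_count Minimum in-background set size to test (default 3).
#' @return Data frame: `set_id`, `description`, `set_size`, `overlap`,
#'   `overlap_genes`, `odds_ratio`, `p`, `q`, sorted by p. Empty (with a
#'   warning) if no set survives filtering.
#' @export
ora_gmt <- function(query, collection, background, min_gene_count = 3) {
  if (min_gene_count < 1) dn_stop("min_gene_count must be >= 1")
  background <- unique(normalize_symbols(background))
  qg <- if (inherits(query, "gene_list")) query$genes else
    normalize_symbols(query)
  qg <- intersect(qg, background)
  rows <- list()
  for (id in names(collection)) {
    members <- intersect(unique(normalize_symbols(collection[[id]]$genes)),
                         background)
    if (length(members) < min_gene_count) next
    ov <- intersect(members, qg)
    ht <- hyper_test(length(ov), length(members), length(qg),
                     length(background))
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = id, description = collection[[id]]$description,
      set_size = length(members), overlap = length(ov),
      overlap_genes = paste(sort(ov), collapse = ","),
      odds_ratio = ht$odds_ratio, p = ht$p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("no gene sets left after min_gene_count filtering", call. = FALSE)
    return(data.frame(set_id = character(), description = character(),
                      set_size = integer(), overlap = integer(),
                      overlap_genes = character(), odds_ratio = numeric(),
                      p = numeric(), q = numeric()))
  }
  out <- do.call(rbind, rows)
  out$q <- adjust_pvalues(out$p, "bh")
  out[order(out$p), , drop = FALSE]
}

#' Bonferroni threshold for the heritability test family
#'
#' `alpha / (n_modules * n_gwas)`: the significance cut-off when every
#' module annotation is tested against every GWAS within a network.
#'
#' @param n_modules Number of modules tested (>= 1).
#' @param n_gwas Number of GWAS tested (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return The threshold.
#' @export
bonferroni_threshold <- function(n_modules, n_gwas, alpha = 0.05) {
  if (n_modules < 1 || n_gwas < 1) dn_stop("counts must be >= 1")
  alpha / (n_modules * n_gwas)
}
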