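#' Gene-by-cell-type specificity matrix
#'
#' Specificity of gene g in cell type c is the proportion of g's total
#' expression attributable to c: the mean expression of g over cells of type
#' c divided by the sum of those per-type means across all types. Rows sum to
#' one; a value of 1 means the gene is expressed only in that type. Genes
#' whose per-type means are all zero carry no signal and are dropped (logged).
#' Per-type means use all cells of the type, zeros included. Whether the
#' input counts are depth-normalized first is the caller's choice; the
#' matrix is taken as given.
#'
#' @param counts Genes x cells numeric matrix with row and column names.
#' @param cell_types Character vector of per-cell type labels (length =
#'   ncol(counts)), or a data frame with columns `cell_id`, `cell_type`.
#' @return Genes x cell-types matrix of class `specificity_matrix`.
#' @export
compute_specificity <- function(counts, cell_types) {
  if (is.data.frame(cell_types)) {
    ct <- cell_types$cell_type[match(colnames(counts), cell_types$cell_id)]
    if (anyNA(ct)) dn_stop("cells missing annotation")
    cell_types <- ct
  }
  if (length(cell_types) != ncol(counts))
    dn_stop("cell_types length must equal ncol(counts)")
  types <- unique(cell_types)
  if (length(types) < 2L) dn_stop("specificity undefined for a single cell type")
  # per-type mean expression: genes x types
  m <- vapply(types, function(t)
    rowMeans(counts[, cell_types == t, drop = FALSE]), numeric(nrow(counts)))
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero))
    dn_log("specificity", sprintf("dropped %d gene(s) with zero expression",
                                  sum(zero)))
  s <- m[!zero, , drop = FALSE] / tot[!zero]
  structure(s, class = c("specificity_matrix", class(s)))
}

#' Compare specificity profiles between two datasets
#'
#' Spearman rank correlation (ties mid-ranked) of the specificity of a gene
#' list in one cell type of dataset A against one cell type of dataset B,
#' over the genes present in both matrices.
#'
#' @param sA,sB Specificity matrices from [compute_specificity()].
#' @param genes A [gene_list()] or character vector restricting the genes.
#' @param cell_type_pair Length-2 character vector: the column of `sA` and
#'   the column of `sB` to compare.
#' @return List: `rho`, `p` (two-sided), `n_genes`.
#' @export
compare_specificity <- function(sA, sB, genes, cell_type_pair) {
  g <- if (inherits(genes, "gene_list")) genes$genes else
    normalize_symbols(genes)
  rownames(sA) <- toupper(trimws(rownames(sA)))
  rownames(sB) <- toupper(trimws(rownames(sB)))
  shared <- intersect(intersect(g, rownames(sA)), rownames(sB))
  if (length(shared) < 3L)
    dn_stop("fewer than 3 shared genes between specificity matrices")
  x <- sA[shared, cell_type_pair[1]]
  y <- sB[shared, cell_type_pair[2]]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_genes = length(shared))
}

#' Write a specificity matrix as TSV (genes in rows, header of cell types)
#' @param s Matrix from [compute_specificity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specificity <- function(s, path) {
  df <- data.frame(gene = rownames(s), as.data.frame(unclass(s)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
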