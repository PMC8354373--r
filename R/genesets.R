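#' Construct a gene list
#'
#' A `gene_list` is an ordered set of unique, upper-cased gene symbols with
#' optional per-gene metadata (disease classification, inheritance mode).
#'
#' @param name Label for the list.
#' @param genes Character vector of gene symbols. Case-insensitive duplicates
#'   are collapsed (first occurrence kept).
#' @param classification Optional character vector, one entry per input gene,
#'   e.g. `"Isolated dystonia"`.
#' @param inheritance Optional character vector, one entry per input gene.
#' @return A `gene_list` object: a list with elements `name`, `genes`, and a
#'   `meta` data frame keyed by symbol.
#' @export
gene_list <- function(name, genes, classification = NULL, inheritance = NULL) {
  raw <- normalize_symbols(genes)
  if (length(raw) == 0L) dn_stop("empty gene list")
  keep <- !duplicated(raw)
  n_dup <- sum(!keep)
  if (n_dup > 0L)
    dn_log("genesets", sprintf("dropped %d duplicate symbol(s) from '%s'",
                               n_dup, name))
  idx <- which(nzchar(trimws(as.character(genes))))[keep]
  meta <- data.frame(
    gene = raw[keep],
    classification = if (is.null(classification)) NA_character_ else
      as.character(classification)[idx],
    inheritance = if (is.null(inheritance)) NA_character_ else
      as.character(inheritance)[idx],
    stringsAsFactors = FALSE
  )
  structure(list(name = name, genes = raw[keep], meta = meta),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> %s: %d genes\n", x$name, length(x$genes)))
  cat(strwrap(paste(x$genes, collapse = ", "), width = 76), sep = "\n")
  invisible(x)
}

#' Curated dystonia gene list
#'
#' Returns the packaged list of 28 confirmed Mendelian dystonia-associated
#' (DYT) genes with their clinical classification (combined, isolated or
#' paroxysmal dystonia) and inheritance mode. Unconfirmed candidates (CIZ1,
#' COL6A3, RELN) are not part of the fixture.
#'
#' @return A [gene_list()] of 28 symbols.
#' @export
dyt_genes <- function() {
  path <- system.file("extdata", "dyt_genes.tsv", package = "dytnet",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gl <- gene_list("DYT genes", tab$gene,
                  classification = tab$classification,
                  inheritance = tab$inheritance)
  gl$meta$phenotype <- tab$phenotype[match(gl$meta$gene,
                                           toupper(tab$gene))]
  gl
}

#' Read a gene list from disk
#'
#' Accepts either one symbol per line or a two-column tab-separated file
#' (symbol, classification). Symbols are upper-cased and de-duplicated; the
#' number of duplicates removed is logged.
#'
#' @param path File path.
#' @param name Label for the resulting list (defaults to the file name).
#' @return A [gene_list()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) dn_stop("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) dn_stop("empty gene list")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, "", 1L)
  cls <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else
    NA_character_, "")
  gene_list(name, genes,
            classification = if (all(is.na(cls))) NULL else cls)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: tab-separated lines `id<TAB>description<TAB>member...`.
#' Lines with fewer than three fields are an error (reported with the line
#' number); sets whose member list is empty after symbol normalization are
#' rejected with a warning.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: named list of
#'   `list(description=, genes=)`, one element per set id.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) dn_stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      dn_stop(sprintf("malformed GMT line %d: fewer than 3 tab fields", i))
    id <- f[[1L]]
    if (!is.null(sets[[id]])) dn_stop("duplicate set id: ", id)
    members <- unique(normalize_symbols(f[-(1:2)]))
    if (length(members) == 0L) {
      warning("GMT set '", id, "' has no members after normalization; skipped",
              call. = FALSE)
      next
    }
    sets[[id]] <- list(description = f[[2L]], genes = members)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param collection A `gene_set_collection` as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    s <- collection[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Intersection of a gene list with a set of symbols
#'
#' Case-insensitive, order-invariant intersection; used e.g. to count how
#' many curated disease genes fall inside a co-expression module.
#'
#' @param a A [gene_list()] or character vector.
#' @param b Character vector of symbols.
#' @return List with `n` (integer size) and `members` (sorted symbols).
#' @export
intersect_genes <- function(a, b) {
  ga <- if (inherits(a, "gene_list")) a$genes else normalize_symbols(a)
  gb <- unique(normalize_symbols(b))
  members <- sort(intersect(unique(ga), gb))
  list(n = length(members), members = members)
}
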