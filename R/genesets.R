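#' Normalize a gene symbol
#'
#' Deterministic, offline canonicalization used everywhere gene identity
#' matters: trim whitespace, uppercase, then map through an optional
#' user-supplied alias table (e.g. old symbol -> current HGNC symbol).
#' The function is idempotent provided the alias table maps onto
#' canonical symbols.
#'
#' @param raw Character vector of raw symbols.
#' @param aliases Optional named character vector `c(ALIAS = "SYMBOL")`;
#'   keys are matched after uppercasing.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_gene_symbol(" casp3 ")              # "CASP3"
#' normalize_gene_symbol("p53", c(P53 = "TP53")) # "TP53"
#' @export
normalize_gene_symbol <- function(raw, aliases = NULL) {
  sym <- toupper(trimws(as.character(raw)))
  if (any(!nzchar(sym)) || anyNA(sym)) {
    stop("empty or missing gene symbol", call. = FALSE)
  }
  if (!is.null(aliases)) {
    names(aliases) <- toupper(trimws(names(aliases)))
    aliases[] <- toupper(trimws(aliases))
    hit <- match(sym, names(aliases))
    sym[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  sym
}

#' Read a gene list
#'
#' One symbol per line; an optional second tab-separated field is a source
#' tag (database of origin). Symbols are normalized and deduplicated.
#'
#' @param path Path to the gene-list file.
#' @param aliases Optional alias table passed to [normalize_gene_symbol()].
#' @param label Label for the set (e.g. the disease name).
#' @return A list with `label`, `genes` (sorted unique character vector)
#'   and `sources` (named integer vector: genes contributed per source
#'   tag, before deduplication).
#' @export
read_gene_list <- function(path, aliases = NULL, label = "gene_set") {
  lines <- read_text_lines(path)
  if (length(lines) == 0) {
    return(list(label = label, genes = character(0),
                sources = integer(0)))
  }
  parts <- strsplit(lines, "\t")
  genes <- normalize_gene_symbol(vapply(parts, `[[`, "", 1L), aliases)
  src <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "unspecified",
                "")
  list(label = label,
       genes = sort(unique(genes)),
       sources = c(table(src)))
}

#' Read a GMT annotation collection
#'
#' The GMT format carries one gene set per line:
#' `term<TAB>description<TAB>gene1<TAB>gene2...`. Genes are normalized and
#' deduplicated within each term; empty terms and duplicate term ids are
#' rejected.
#'
#' @param path Path to the GMT file.
#' @param aliases Optional alias table passed to [normalize_gene_symbol()].
#' @return A list of class `annotation_collection`: `terms` (named list of
#'   character vectors), `descriptions` (named character vector) and
#'   `universe` (`NULL` unless set explicitly; see [enrich_gene_set()]).
#' @export
read_gmt <- function(path, aliases = NULL) {
  lines <- read_text_lines(path)
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1],
         " is malformed (need term, description, >= 1 gene)", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  terms <- lapply(parts, function(p) {
    genes <- p[3:length(p)]
    genes <- genes[nzchar(trimws(genes))]
    if (length(genes) == 0) return(character(0))
    sort(unique(normalize_gene_symbol(genes, aliases)))
  })
  empty <- lengths(terms) == 0
  if (any(empty)) {
    stop("GMT term '", ids[empty][1], "' has no genes", call. = FALSE)
  }
  names(terms) <- ids
  descriptions <- vapply(parts, `[[`, "", 2L)
  names(descriptions) <- ids
  structure(list(terms = terms, descriptions = descriptions,
                 universe = NULL),
            class = "annotation_collection")
}

#' Write a GMT annotation collection
#'
#' @param annotations An `annotation_collection` (see [read_gmt()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_collection"))
  ids <- names(annotations$terms)
  lines <- vapply(ids, function(id) {
    paste(c(id, annotations$descriptions[[id]], annotations$terms[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("annotation_collection:", length(x$terms), "terms,",
      length(unique(unlist(x$terms, use.names = FALSE))), "distinct genes\n")
  invisible(x)
}

#' Read a compound-target association table
#'
#' Two or three tab-separated columns: compound id, gene symbol, optional
#' source tag. Gene symbols are normalized; exact duplicate
#' (compound, gene) pairs are collapsed.
#'
#' @param path Path to the association file.
#' @param aliases Optional alias table passed to [normalize_gene_symbol()].
#' @return A data.frame with columns `mol_id`, `gene`, `source`.
#' @export
read_associations <- function(path, aliases = NULL) {
  lines <- read_text_lines(path)
  if (length(lines) == 0) {
    return(data.frame(mol_id = character(0), gene = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("association line ", which(nf < 2)[1],
         " has fewer than 2 fields", call. = FALSE)
  }
  df <- data.frame(
    mol_id = trimws(vapply(parts, `[[`, "", 1L)),
    gene = normalize_gene_symbol(vapply(parts, `[[`, "", 2L), aliases),
    source = vapply(parts,
                    function(p) if (length(p) >= 3) p[3] else "unspecified",
                    ""),
    stringsAsFactors = FALSE
  )
  df[!duplicated(df[c("mol_id", "gene")]), , drop = FALSE]
}
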