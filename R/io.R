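#' Read a compound table
#'
#' Reads a tab- or comma-separated table of herbal compounds carrying the
#' two ADME screening properties: oral bioavailability (OB, in percent)
#' and drug-likeness (DL, dimensionless in \[0, 1\]). Column names are
#' mapped through `dialect`, so tables exported from different sources can
#' be read without editing.
#'
#' @param path Path to a TSV/CSV file. Lines starting with `#` are
#'   comments. The separator is sniffed from the header (tab wins over
#'   comma).
#' @param dialect Named character vector mapping the canonical names
#'   `mol_id`, `name`, `ob`, `dl` to the column names used in the file.
#' @return A data.frame with columns `mol_id`, `name`, `ob`, `dl`,
#'   `is_active` (initialised to `FALSE`; set by
#'   [filter_active_compounds()]), rows in file order.
#' @examples
#' path <- system.file("extdata", "cassiae_semen_compounds.tsv",
#'                     package = "herbnetpharm")
#' head(read_compound_table(path))
#' @export
read_compound_table <- function(path,
                                dialect = c(mol_id = "mol_id", name = "name",
                                            ob = "ob", dl = "dl")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- read_text_lines(path)
  if (length(first) == 0) {
    stop("compound table is empty: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", first[1])) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          comment.char = "#", quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  need <- c("mol_id", "name", "ob", "dl")
  if (!all(need %in% names(dialect))) {
    stop("`dialect` must map all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (canon in need) {
    col <- dialect[[canon]]
    if (!col %in% names(df)) {
      stop("compound table is missing column '", col, "' (for ", canon, ")",
           call. = FALSE)
    }
  }
  out <- data.frame(
    mol_id = df[[dialect[["mol_id"]]]],
    name = df[[dialect[["name"]]]],
    ob = suppressWarnings(as.numeric(df[[dialect[["ob"]]]])),
    dl = suppressWarnings(as.numeric(df[[dialect[["dl"]]]])),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$ob) | is.na(out$dl))
  if (length(bad) > 0) {
    stop("non-numeric ob/dl at data row ", bad[1], call. = FALSE)
  }
  validate_compounds(out)
  out$is_active <- logical(nrow(out))
  out
}

validate_compounds <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("mol_id", "ob", "dl") %in% names(records)))
  if (nrow(records) == 0) return(invisible(records))
  if (any(!nzchar(records$mol_id))) {
    stop("empty mol_id in compound table", call. = FALSE)
  }
  if (anyDuplicated(records$mol_id)) {
    stop("duplicate mol_id: ",
         records$mol_id[duplicated(records$mol_id)][1], call. = FALSE)
  }
  if (any(records$ob < 0)) stop("ob must be >= 0", call. = FALSE)
  if (any(records$dl < 0 | records$dl > 1)) {
    stop("dl must lie in [0, 1]", call. = FALSE)
  }
  invisible(records)
}

#' Read an edge list as an interaction graph
#'
#' Each non-comment, non-empty line must contain at least two whitespace-
#' or tab-separated fields; additional fields (weights, interaction types)
#' are ignored. Self-loops are dropped and duplicate or reversed-duplicate
#' edges collapsed; the count of removed records is kept in the graph's
#' `n_dropped` field.
#'
#' @param path Path to the edge-list file.
#' @return An `interaction_graph`.
#' @export
read_edge_list <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0) return(interaction_graph())
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("edge list line ", which(nf < 2)[1], " has fewer than 2 fields",
         call. = FALSE)
  }
  e <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  interaction_graph(edges = e)
}

#' Read a Cytoscape SIF file
#'
#' Lines are `source<TAB or space>interaction-type<TAB or space>target...`;
#' any interaction-type token is accepted. Lines with a single field
#' declare an isolated node.
#'
#' @param path Path to the SIF file.
#' @return An `interaction_graph`.
#' @export
read_sif <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0) return(interaction_graph())
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf == 2)) {
    stop("SIF line ", which(nf == 2)[1],
         " has 2 fields; expected 1 (isolated node) or >= 3", call. = FALSE)
  }
  singles <- unlist(parts[nf == 1], use.names = FALSE)
  e <- NULL
  multi <- parts[nf >= 3]
  if (length(multi) > 0) {
    e <- do.call(rbind, lapply(multi, function(p) {
      cbind(p[1], p[3:length(p)])
    }))
  }
  nodes <- unique(c(singles, as.vector(t(e))))
  interaction_graph(nodes = nodes, edges = e)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines[nzchar(trimws(lines))]
}

#' Write a graph to file
#'
#' Supported formats: `"sif"` (Cytoscape simple interaction format, one
#' `u pp v` line per undirected edge, isolated nodes as bare ids),
#' `"edge-list"` (two tab-separated columns; isolated nodes are not
#' representable and are silently omitted), and `"graphml"`.
#'
#' @param g An `interaction_graph`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"edge-list"`.
#' @return Invisibly, `path`.
#' @export
write_graph <- function(g, path, format = c("sif", "graphml", "edge-list")) {
  stopifnot_graph(g)
  format <- match.arg(format)
  if (format == "sif") {
    iso <- setdiff(g$nodes, unique(as.vector(t(g$edges))))
    lines <- character(0)
    if (nrow(g$edges) > 0) {
      lines <- paste(g$edges[, 1], "pp", g$edges[, 2], sep = "\t")
    }
    writeLines(c(lines, iso), path, useBytes = TRUE)
  } else if (format == "edge-list") {
    lines <- if (nrow(g$edges) > 0) {
      paste(g$edges[, 1], g$edges[, 2], sep = "\t")
    } else character(0)
    writeLines(lines, path, useBytes = TRUE)
  } else {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML file
#'
#' @param path Path to a GraphML file.
#' @return An `interaction_graph`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  from_igraph(igraph::read_graph(path, format = "graphml"))
}
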