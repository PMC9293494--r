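#' Build the compound-target bipartite network
#'
#' Nodes are the active compounds that have at least one target
#' association, plus their targets; edges are the distinct
#' (compound, gene) pairs. Associations referring to compounds absent
#' from `active` are dropped (their count is returned), mirroring the
#' situation where a screened-in compound has no retrievable target
#' information and therefore contributes no edges.
#'
#' @param active Data.frame of active compounds (needs `mol_id`).
#' @param assoc Data.frame of associations (needs `mol_id`, `gene`).
#' @return A list with `graph` (a bipartite `interaction_graph` with
#'   `node_kind` set), `n_dropped_assoc` (associations whose compound was
#'   not in `active`), and `compounds_without_targets` (active compound
#'   ids absent from the network).
#' @export
build_compound_target_network <- function(active, assoc) {
  stopifnot(is.data.frame(active), "mol_id" %in% names(active),
            is.data.frame(assoc),
            all(c("mol_id", "gene") %in% names(assoc)))
  keep <- assoc$mol_id %in% active$mol_id
  n_dropped <- sum(!keep)
  assoc <- assoc[keep, , drop = FALSE]
  assoc <- assoc[!duplicated(assoc[c("mol_id", "gene")]), , drop = FALSE]
  clash <- intersect(unique(assoc$mol_id), unique(assoc$gene))
  if (length(clash) > 0) {
    stop("identifier used as both compound and gene: ", clash[1],
         call. = FALSE)
  }
  compounds <- active$mol_id[active$mol_id %in% assoc$mol_id]
  genes <- sort(unique(assoc$gene))
  kind <- c(rep("compound", length(compounds)), rep("gene", length(genes)))
  names(kind) <- c(compounds, genes)
  g <- interaction_graph(nodes = c(compounds, genes),
                         edges = cbind(assoc$mol_id, assoc$gene),
                         node_kind = kind)
  list(graph = g,
       n_dropped_assoc = n_dropped,
       compounds_without_targets = setdiff(active$mol_id, compounds))
}

#' Degree ranking of one node class
#'
#' Ranks compounds (or genes) of a bipartite network by degree, i.e. by
#' how many partners of the other class they touch. Ties are broken by id
#' so tables are reproducible.
#'
#' @param g A bipartite `interaction_graph` with `node_kind` set.
#' @param kind `"compound"` or `"gene"`.
#' @return Data.frame with columns `id`, `degree`, sorted by degree
#'   descending then id ascending.
#' @export
degree_ranking <- function(g, kind = c("compound", "gene")) {
  stopifnot_graph(g)
  kind <- match.arg(kind)
  if (is.null(g$node_kind)) {
    stop("graph has no `node_kind`; build it with ",
         "build_compound_target_network()", call. = FALSE)
  }
  ids <- g$nodes[g$node_kind == kind]
  deg <- graph_degree(g)[ids]
  out <- data.frame(id = ids, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Induce a PPI subnetwork on a seed gene set
#'
#' Restricts a background interactome to the seed genes: kept edges are
#' exactly the background edges with both endpoints in the seed set.
#' Nodes left without any connection are removed when `drop_isolated` is
#' `TRUE` (the usual convention when visualising disease or target PPI
#' networks). Seeds missing from the background are reported, not an
#' error: gene lists routinely contain symbols absent from any curated
#' interactome snapshot.
#'
#' @param background An `interaction_graph` interactome.
#' @param seeds Character vector of normalized gene symbols.
#' @param drop_isolated Remove degree-0 nodes from the result
#'   (default `TRUE`).
#' @return A list with `graph`, `absent` (seeds not in the background) and
#'   `isolated` (seeds present but connection-free, removed when
#'   `drop_isolated`).
#' @export
induced_ppi_subgraph <- function(background, seeds, drop_isolated = TRUE) {
  stopifnot_graph(background)
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("empty seed set", call. = FALSE)
  absent <- setdiff(seeds, background$nodes)
  sub <- induced_subgraph(background, seeds)
  deg <- graph_degree(sub)
  isolated <- names(deg)[deg == 0]
  if (drop_isolated && length(isolated) > 0) {
    sub <- induced_subgraph(sub, names(deg)[deg > 0])
  }
  list(graph = sub, absent = absent, isolated = isolated)
}

#' Merge compound-target and disease-target PPI networks
#'
#' Induces the background interactome on the union of the two seed sets
#' (dropping connection-free nodes) and labels each retained node by
#' provenance: `compound` (compound target only), `disease` (disease gene
#' only) or `shared` (both).
#'
#' @param compound_targets Character vector of compound-target symbols.
#' @param disease_targets Character vector of disease-gene symbols.
#' @param background An `interaction_graph` interactome.
#' @return A list with `graph`, `provenance` (named character vector over
#'   the retained nodes), `absent`, `isolated`.
#' @export
merge_target_networks <- function(compound_targets, disease_targets,
                                  background) {
  compound_targets <- unique(as.character(compound_targets))
  disease_targets <- unique(as.character(disease_targets))
  if (length(compound_targets) == 0 || length(disease_targets) == 0) {
    stop("both target sets must be non-empty", call. = FALSE)
  }
  res <- induced_ppi_subgraph(background,
                              union(compound_targets, disease_targets),
                              drop_isolated = TRUE)
  nodes <- res$graph$nodes
  provenance <- ifelse(nodes %in% compound_targets & nodes %in% disease_targets,
                       "shared",
                       ifelse(nodes %in% compound_targets, "compound",
                              "disease"))
  names(provenance) <- nodes
  list(graph = res$graph, provenance = provenance,
       absent = res$absent, isolated = res$isolated)
}

#' Shared targets of two gene sets
#'
#' The intersection of compound targets and disease genes - the genes a
#' herb can act on that are also implicated in the disease.
#'
#' @param compound_targets,disease_targets Character vectors of normalized
#'   symbols.
#' @return Sorted character vector.
#' @export
shared_targets <- function(compound_targets, disease_targets) {
  sort(intersect(unique(as.character(compound_targets)),
                 unique(as.character(disease_targets))))
}
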