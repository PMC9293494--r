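#' Undirected simple interaction graph
#'
#' `interaction_graph()` is the container every stage of the pipeline works
#' on: an undirected simple graph over character node identifiers (gene
#' symbols, or compound ids plus gene symbols in the bipartite
#' compound-target network). Self-loops are dropped and duplicate or
#' reversed-duplicate edges collapsed on construction, so downstream code
#' can rely on each unordered pair being stored exactly once.
#'
#' @param nodes Character vector of node identifiers. Defaults to the union
#'   of edge endpoints; extra isolated nodes may be listed explicitly.
#' @param edges Two-column character matrix (or data.frame) of endpoints,
#'   one undirected edge per row. May be `NULL` for an edgeless graph.
#' @param node_kind Optional named character vector mapping node id to
#'   `"compound"` or `"gene"` for bipartite networks.
#' @return An object of class `interaction_graph` with elements `nodes`
#'   (character), `edges` (two-column character matrix, endpoints sorted
#'   within each row, rows unique), `node_kind`, and `n_dropped` (count of
#'   self-loops and duplicates removed during construction).
#' @examples
#' g <- interaction_graph(edges = cbind(c("A", "B", "B"), c("B", "A", "C")))
#' graph_size(g)  # 2 distinct edges
#' @export
interaction_graph <- function(nodes = NULL, edges = NULL, node_kind = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2) stop("`edges` must have two columns", call. = FALSE)
    edges <- edges[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
  } else {
    edges <- matrix(character(0), ncol = 2)
  }
  n_in <- nrow(edges)
  if (n_in > 0) {
    loops <- edges[, 1] == edges[, 2]
    edges <- edges[!loops, , drop = FALSE]
    if (nrow(edges) > 0) {
      edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
      edges <- edges[!duplicated(paste(edges[, 1], edges[, 2], sep = "\r")), ,
                     drop = FALSE]
    }
  }
  n_dropped <- n_in - nrow(edges)
  endpoint_nodes <- unique(as.vector(t(edges)))
  if (is.null(nodes)) {
    nodes <- endpoint_nodes
  } else {
    nodes <- unique(as.character(nodes))
    missing <- setdiff(endpoint_nodes, nodes)
    if (length(missing) > 0) {
      stop("edge endpoints absent from `nodes`: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (anyNA(nodes) || any(!nzchar(nodes))) {
    stop("node identifiers must be non-empty strings", call. = FALSE)
  }
  if (!is.null(node_kind)) {
    node_kind <- node_kind[nodes]
    names(node_kind) <- nodes
    bad <- !node_kind %in% c("compound", "gene")
    if (any(bad | is.na(node_kind))) {
      stop("`node_kind` must label every node as 'compound' or 'gene'",
           call. = FALSE)
    }
  }
  structure(
    list(nodes = nodes, edges = edges, node_kind = node_kind,
         n_dropped = n_dropped),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  if (!is.null(x$node_kind)) {
    tab <- table(x$node_kind)
    cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Graph order and size
#'
#' @param g An `interaction_graph`.
#' @return `graph_order()` the number of nodes; `graph_size()` the number of
#'   distinct undirected edges.
#' @export
graph_order <- function(g) length(g$nodes)

#' @rdname graph_order
#' @export
graph_size <- function(g) nrow(g$edges)

stopifnot_graph <- function(g) {
  if (!inherits(g, "interaction_graph")) {
    stop("expected an `interaction_graph`", call. = FALSE)
  }
  invisible(g)
}

#' Adjacency list of a graph
#'
#' Integer-index adjacency used by the centrality and module-detection
#' code; position i of the result holds the (sorted) indices of the
#' neighbours of `g$nodes[i]`.
#'
#' @param g An `interaction_graph`.
#' @return List of integer vectors, one per node, named by node id.
#' @keywords internal
adjacency_list <- function(g) {
  stopifnot_graph(g)
  n <- length(g$nodes)
  adj <- rep(list(integer(0)), n)
  if (nrow(g$edges) > 0) {
    i <- match(g$edges[, 1], g$nodes)
    j <- match(g$edges[, 2], g$nodes)
    ii <- c(i, j)
    jj <- c(j, i)
    ord <- order(ii, jj)
    adj_split <- split(jj[ord], factor(ii[ord], levels = seq_len(n)))
    adj <- unname(adj_split)
  }
  names(adj) <- g$nodes
  adj
}

#' Node degrees
#'
#' @param g An `interaction_graph`.
#' @return Named integer vector of degrees in node order.
#' @export
graph_degree <- function(g) {
  stopifnot_graph(g)
  d <- integer(length(g$nodes))
  names(d) <- g$nodes
  if (nrow(g$edges) > 0) {
    tab <- table(factor(c(g$edges[, 1], g$edges[, 2]), levels = g$nodes))
    d[] <- as.integer(tab)
  }
  d
}

#' Subgraph induced on a node set
#'
#' Keeps the listed nodes (in their original order) and every edge with
#' both endpoints among them.
#'
#' @param g An `interaction_graph`.
#' @param nodes Character vector of node ids; ids absent from `g` are
#'   ignored.
#' @return An `interaction_graph`.
#' @export
induced_subgraph <- function(g, nodes) {
  stopifnot_graph(g)
  keep <- g$nodes[g$nodes %in% nodes]
  e <- g$edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  kind <- if (!is.null(g$node_kind)) g$node_kind[keep] else NULL
  interaction_graph(nodes = keep, edges = e, node_kind = kind)
}

#' Convert to and from igraph
#'
#' Interoperability helpers; `as_igraph()` is also what the GraphML
#' reader/writer is built on.
#'
#' @param g An `interaction_graph`.
#' @return `as_igraph()` an [igraph::graph] object; `from_igraph()` an
#'   `interaction_graph`.
#' @export
as_igraph <- function(g) {
  stopifnot_graph(g)
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, length(g$nodes), name = g$nodes)
  if (nrow(g$edges) > 0) {
    ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  }
  ig
}

#' @rdname as_igraph
#' @param ig An igraph object with a `name` vertex attribute.
#' @export
from_igraph <- function(ig) {
  nodes <- igraph::vertex_attr(ig, "name")
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(ig)))
  e <- igraph::as_edgelist(ig, names = TRUE)
  interaction_graph(nodes = nodes, edges = e)
}

#' Edge identity helper
#'
#' Canonical "u|v" keys (endpoints sorted) for set comparisons in tests
#' and reports.
#'
#' @param g An `interaction_graph`.
#' @return Character vector of canonical edge keys.
#' @export
edge_keys <- function(g) {
  stopifnot_graph(g)
  if (nrow(g$edges) == 0) return(character(0))
  paste(g$edges[, 1], g$edges[, 2], sep = "|")
}
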