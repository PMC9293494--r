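#' Six node-centrality measures for key-target screening
#'
#' The key-target screen ranks every node of an undirected PPI network on
#' six topological measures - degree (DC), closeness (CC), betweenness
#' (BC), eigenvector (EC), local average connectivity (LAC) and the
#' edge-clustering-based network centrality (NC) - and keeps the nodes
#' that exceed the network-wide mean on all six at once. The conventions
#' follow the CytoNCA family: BC is unnormalized with each unordered pair
#' counted once, CC is component-restricted, LAC and NC are the
#' neighbourhood-density statistics defined below.
#'
#' * `degree_centrality()`: number of incident edges.
#' * `closeness_centrality()`: `(|C_v| - 1) / sum of d(v, u)` over `v`'s
#'   connected component `C_v` (0 for isolated nodes); distances by
#'   unweighted breadth-first search.
#' * `betweenness_centrality()`: `sum over pairs s < t (s, t != v)` of
#'   `sigma_st(v) / sigma_st`, the fraction of shortest s-t paths through
#'   `v`, by Brandes' single-source accumulation.
#' * `eigenvector_centrality()`: principal eigenvector of the adjacency
#'   matrix by power iteration from the uniform vector, L2-normalized,
#'   entries nonnegative.
#' * `local_average_connectivity()`: `2 e(N(v)) / |N(v)|` where `e(N(v))`
#'   is the edge count of the subgraph induced by `v`'s neighbours - the
#'   average degree of the neighbours within that subgraph.
#' * `network_centrality()`: sum over `v`'s incident edges of the edge
#'   clustering coefficient `ECC(u, v) = z_uv / min(d_u - 1, d_v - 1)`,
#'   with `z_uv` the number of common neighbours and `ECC = 0` when the
#'   denominator vanishes (an endpoint of degree 1).
#'
#' @param g An `interaction_graph`.
#' @return Named numeric vector over `g$nodes`.
#' @name centrality-measures
NULL

#' @rdname centrality-measures
#' @export
degree_centrality <- function(g) {
  d <- graph_degree(g)
  storage.mode(d) <- "double"
  d
}

#' @rdname centrality-measures
#' @export
closeness_centrality <- function(g) {
  stopifnot_graph(g)
  adj <- adjacency_list(g)
  n <- length(adj)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- bfs_distances(adj, s)
    reach <- which(dist >= 0 & seq_len(n) != s)
    if (length(reach) > 0) cc[s] <- length(reach) / sum(dist[reach])
  }
  names(cc) <- g$nodes
  cc
}

# BFS distances from source s; -1 for unreachable nodes.
bfs_distances <- function(adj, s) {
  n <- length(adj)
  dist <- rep(-1L, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (u in adj[[v]]) {
      if (dist[u] < 0L) {
        dist[u] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- u
      }
    }
  }
  dist
}

#' @rdname centrality-measures
#' @export
betweenness_centrality <- function(g) {
  stopifnot_graph(g)
  adj <- adjacency_list(g)
  n <- length(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # Brandes: BFS pass recording predecessors and path counts
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    pred <- rep(list(integer(0)), n)
    order_visited <- integer(n)
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      order_visited[head] <- v
      head <- head + 1L
      for (u in adj[[v]]) {
        if (dist[u] < 0L) {
          dist[u] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- u
        }
        if (dist[u] == dist[v] + 1L) {
          sigma[u] <- sigma[u] + sigma[v]
          pred[[u]] <- c(pred[[u]], v)
        }
      }
    }
    # dependency accumulation in reverse visit order
    delta <- numeric(n)
    for (idx in rev(seq_len(tail))) {
      w <- order_visited[idx]
      for (v in pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair was accumulated from both endpoints
  names(bc) <- g$nodes
  bc
}

#' @rdname centrality-measures
#' @param tol Convergence tolerance on the max-norm difference of
#'   successive normalized iterates (default 1e-10).
#' @param max_iter Iteration cap (default 10000); non-convergence is
#'   signalled via the `converged` attribute and a warning, never
#'   silently.
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 10000L) {
  stopifnot_graph(g)
  if (graph_size(g) == 0) {
    stop("eigenvector centrality needs a graph with at least one edge",
         call. = FALSE)
  }
  adj <- adjacency_list(g)
  n <- length(adj)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # iterate on A + I: same principal eigenvector, but strictly dominant
    # eigenvalue, so bipartite graphs (symmetric spectrum) still converge
    x_new <- x + vapply(seq_len(n), function(v) sum(x[adj[[v]]]), 0)
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) break  # iterate vanished (can only happen without edges)
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged) {
    warning("eigenvector centrality did not converge in ", max_iter,
            " iterations", call. = FALSE)
  }
  names(x) <- g$nodes
  attr(x, "converged") <- converged
  x
}

#' @rdname centrality-measures
#' @export
local_average_connectivity <- function(g) {
  stopifnot_graph(g)
  adj <- adjacency_list(g)
  n <- length(adj)
  lac <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k == 0) next
    e_nb <- count_edges_among(adj, nb)
    lac[v] <- 2 * e_nb / k
  }
  names(lac) <- g$nodes
  lac
}

# number of edges of the subgraph induced by node indices `nb`
count_edges_among <- function(adj, nb) {
  if (length(nb) < 2) return(0L)
  in_set <- logical(length(adj))
  in_set[nb] <- TRUE
  tot <- 0L
  for (u in nb) tot <- tot + sum(in_set[adj[[u]]])
  tot %/% 2L
}

#' @rdname centrality-measures
#' @export
network_centrality <- function(g) {
  stopifnot_graph(g)
  adj <- adjacency_list(g)
  n <- length(adj)
  deg <- lengths(adj)
  nc <- numeric(n)
  if (nrow(g$edges) > 0) {
    i <- match(g$edges[, 1], g$nodes)
    j <- match(g$edges[, 2], g$nodes)
    for (e in seq_along(i)) {
      u <- i[e]; v <- j[e]
      denom <- min(deg[u], deg[v]) - 1L
      if (denom <= 0L) next
      z <- length(intersect(adj[[u]], adj[[v]]))
      ecc <- z / denom
      nc[u] <- nc[u] + ecc
      nc[v] <- nc[v] + ecc
    }
  }
  names(nc) <- g$nodes
  nc
}

#' Centrality table over a whole network
#'
#' Computes all six measures described in [centrality-measures] on the
#' same graph and attaches the per-measure arithmetic mean over all
#' nodes, the reference values the key-target screen compares against.
#'
#' @param g An `interaction_graph` with at least one edge.
#' @param tol,max_iter Passed to [eigenvector_centrality()].
#' @return An object of class `centrality_table`: a data.frame with
#'   columns `node`, `dc`, `cc`, `bc`, `ec`, `lac`, `nc` (one row per
#'   node, in graph node order) and an attribute `means` (named numeric
#'   vector of the six column means).
#' @export
centrality_table <- function(g, tol = 1e-10, max_iter = 10000L) {
  stopifnot_graph(g)
  tab <- data.frame(
    node = g$nodes,
    dc = unname(degree_centrality(g)),
    cc = unname(closeness_centrality(g)),
    bc = unname(betweenness_centrality(g)),
    ec = as.numeric(eigenvector_centrality(g, tol = tol,
                                           max_iter = max_iter)),
    lac = unname(local_average_connectivity(g)),
    nc = unname(network_centrality(g)),
    stringsAsFactors = FALSE
  )
  metric_cols <- c("dc", "cc", "bc", "ec", "lac", "nc")
  attr(tab, "means") <- vapply(tab[metric_cols], mean, 0)
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' Screen key nodes by the six-measure above-mean rule
#'
#' A node is a key target when its value exceeds the network-wide mean on
#' every one of the six centrality measures simultaneously (strict `>` by
#' default; `strict = FALSE` uses `>=`). The central network is the
#' subgraph induced on the key targets. An empty key set is a legal
#' outcome: e.g. on a vertex-transitive graph no node can strictly exceed
#' any mean.
#'
#' @param table A `centrality_table` computed on `g`.
#' @param g The `interaction_graph` the table was computed on.
#' @param strict Strict comparison against the means (default `TRUE`).
#' @return A list of class `screening_result`: `key_nodes` (ids sorted by
#'   degree descending then id), `passes` (logical matrix node x metric),
#'   `means`, and `central` (the induced `interaction_graph`).
#' @export
screen_key_nodes <- function(table, g, strict = TRUE) {
  stopifnot(inherits(table, "centrality_table"))
  stopifnot_graph(g)
  if (!identical(table$node, g$nodes)) {
    stop("`table` was not computed on `g` (node sets differ)", call. = FALSE)
  }
  metric_cols <- c("dc", "cc", "bc", "ec", "lac", "nc")
  means <- attr(table, "means")
  cmp <- if (strict) `>` else `>=`
  passes <- vapply(metric_cols,
                   function(m) cmp(table[[m]], means[[m]]),
                   logical(nrow(table)))
  if (is.null(dim(passes))) passes <- matrix(passes, nrow = nrow(table),
                                             dimnames = list(NULL, metric_cols))
  rownames(passes) <- table$node
  key <- table$node[rowSums(passes) == length(metric_cols)]
  deg <- graph_degree(g)[key]
  key <- key[order(-deg, key)]
  structure(
    list(key_nodes = key, passes = passes, means = means,
         central = induced_subgraph(g, key)),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("screening_result:", length(x$key_nodes), "key nodes,",
      graph_size(x$central), "interactions among them\n")
  invisible(x)
}
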