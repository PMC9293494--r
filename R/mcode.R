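#' MCODE parameters
#'
#' Parameters of the seeded greedy dense-module detector, with the
#' published tool defaults: vertex weight percentage 0.2, haircut on,
#' fluff off, minimum module size 3.
#'
#' @param vwp Vertex weight percentage in \[0, 1): a neighbour joins a
#'   module when its weight is at least `(1 - vwp)` times the seed's.
#' @param haircut Remove singly-connected nodes from each module (the
#'   module's 2-core) before scoring.
#' @param fluff Add boundary neighbours whose neighbourhood density
#'   exceeds `fluff_density` after the core expansion.
#' @param fluff_density Density threshold for fluff (default 0.1).
#' @param min_size Discard modules with fewer nodes (default 3).
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.1, min_size = 3L) {
  stopifnot(is.numeric(vwp), length(vwp) == 1, vwp >= 0, vwp < 1,
            is.logical(haircut), is.logical(fluff),
            is.numeric(fluff_density), fluff_density >= 0,
            is.numeric(min_size), min_size >= 2)
  structure(list(vwp = vwp, haircut = isTRUE(haircut),
                 fluff = isTRUE(fluff), fluff_density = fluff_density,
                 min_size = as.integer(min_size)),
            class = "mcode_params")
}

#' MCODE vertex weighting
#'
#' Weight of a node v = k x density of the highest k-core of the subgraph
#' induced by v's closed neighbourhood N\[v\] (v plus its neighbours),
#' where density is `2E / (n (n - 1))`. Nodes whose closed neighbourhood
#' has no edges get weight 0. High weight marks nodes sitting inside
#' locally dense regions, the seeds of the module search.
#'
#' @param g An `interaction_graph`.
#' @return Named numeric vector of weights over `g$nodes`.
#' @export
mcode_weight_nodes <- function(g) {
  stopifnot_graph(g)
  adj <- adjacency_list(g)
  n <- length(adj)
  w <- numeric(n)
  for (v in seq_len(n)) {
    closed <- c(v, adj[[v]])
    if (length(closed) < 2) next
    sub <- local_subgraph(adj, closed)
    core <- highest_k_core(sub)
    if (core$k == 0) next
    m <- length(core$members)
    dens <- if (m < 2) 0 else 2 * core$n_edges / (m * (m - 1))
    w[v] <- core$k * dens
  }
  names(w) <- g$nodes
  w
}

# adjacency (local indices) of the subgraph induced by node indices `members`
local_subgraph <- function(adj, members) {
  pos <- integer(length(adj))
  pos[members] <- seq_along(members)
  lapply(members, function(u) {
    nb <- adj[[u]]
    pos[nb[pos[nb] > 0L]]
  })
}

# highest (maximum-k) k-core of a local adjacency list; returns the core
# order k, member indices (into the local graph) and the induced edge count
highest_k_core <- function(local_adj) {
  n <- length(local_adj)
  deg <- lengths(local_adj)
  alive <- rep(TRUE, n)
  core_num <- integer(n)
  # iterative peeling: remove min-degree vertices, recording core numbers
  k <- 0L
  remaining <- n
  while (remaining > 0) {
    repeat {
      low <- which(alive & deg <= k)
      if (length(low) == 0) break
      for (v in low) {
        alive[v] <- FALSE
        core_num[v] <- k
        remaining <- remaining - 1L
        for (u in local_adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
      }
    }
    if (remaining == 0) break
    k <- k + 1L
  }
  kmax <- max(core_num)
  if (kmax == 0L) {
    return(list(k = 0L, members = integer(0), n_edges = 0L))
  }
  members <- which(core_num >= kmax)
  in_core <- logical(n)
  in_core[members] <- TRUE
  n_edges <- sum(vapply(members,
                        function(v) sum(in_core[local_adj[[v]]]), 0L)) %/% 2L
  list(k = kmax, members = members, n_edges = n_edges)
}

#' Score a candidate module
#'
#' The MCODE cluster score of a node set is its induced density times its
#' size: `score = (2E / (n (n - 1))) * n`. The score equals `n` exactly
#' when the module is a clique, and a 6-node module missing a single edge
#' scores `6 * 14/15 = 5.60`.
#'
#' @param g An `interaction_graph`.
#' @param nodes Character vector of at least two node ids in `g`.
#' @param seed Optional seed node id to record in the result.
#' @return A list of class `module_result`: `nodes` (sorted), `n`,
#'   `n_edges`, `density`, `score`, `seed`.
#' @examples
#' k6 <- interaction_graph(edges = t(combn(LETTERS[1:6], 2)))
#' k6_minus <- interaction_graph(nodes = k6$nodes, edges = k6$edges[-1, ])
#' module_score(k6_minus, LETTERS[1:6])$score  # 5.6
#' @export
module_score <- function(g, nodes, seed = NA_character_) {
  stopifnot_graph(g)
  nodes <- unique(as.character(nodes))
  if (length(nodes) < 2) {
    stop("a module needs at least 2 nodes", call. = FALSE)
  }
  if (!all(nodes %in% g$nodes)) {
    stop("module nodes absent from graph: ",
         paste(utils::head(setdiff(nodes, g$nodes), 3), collapse = ", "),
         call. = FALSE)
  }
  sub <- induced_subgraph(g, nodes)
  n <- graph_order(sub)
  m <- graph_size(sub)
  density <- 2 * m / (n * (n - 1))
  structure(
    list(nodes = sort(nodes), n = n, n_edges = m, density = density,
         score = density * n, seed = seed),
    class = "module_result"
  )
}

#' @export
print.module_result <- function(x, ...) {
  cat(sprintf("module_result: %d nodes, %d edges, density %.3f, score %.2f\n",
              x$n, x$n_edges, x$density, x$score))
  invisible(x)
}

#' Detect dense modules (MCODE)
#'
#' Seeded greedy dense-module detection: nodes are weighted by
#' [mcode_weight_nodes()], then, taking unassigned nodes in decreasing
#' weight order (ties by id) as seeds, each module grows breadth-first by
#' adding unassigned neighbours whose weight is at least
#' `(1 - vwp) * weight(seed)`. Each node belongs to at most one module.
#' With `haircut`, singly-connected nodes are pruned (the module is
#' reduced to its 2-core); with `fluff`, boundary neighbours with dense
#' neighbourhoods are appended (fluffed nodes may overlap between
#' modules, as in the original tool). Modules smaller than `min_size`
#' are discarded.
#'
#' @param g An `interaction_graph`.
#' @param params An [mcode_params()] object.
#' @return List of `module_result` objects sorted by score descending,
#'   ties by size descending then seed id.
#' @export
mcode_find_modules <- function(g, params = mcode_params()) {
  stopifnot_graph(g)
  stopifnot(inherits(params, "mcode_params"))
  if (graph_size(g) == 0) return(list())
  adj <- adjacency_list(g)
  w <- mcode_weight_nodes(g)
  ord <- order(-w, g$nodes)
  assigned <- logical(length(adj))
  modules <- list()
  for (s in ord) {
    if (assigned[s] || w[s] <= 0) next
    threshold <- (1 - params$vwp) * w[s]
    members <- integer(0)
    queue <- s
    seen <- logical(length(adj))
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      members <- c(members, v)
      for (u in adj[[v]]) {
        if (!seen[u] && !assigned[u] && w[u] >= threshold) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    assigned[members] <- TRUE
    if (params$haircut) members <- haircut_2core(adj, members)
    if (params$fluff) {
      members <- fluff_members(adj, members, params$fluff_density)
    }
    if (length(members) >= params$min_size) {
      modules <- c(modules, list(
        module_score(g, g$nodes[members], seed = g$nodes[s])
      ))
    }
  }
  ord2 <- order(-vapply(modules, `[[`, 0, "score"),
                -vapply(modules, `[[`, 0L, "n"),
                vapply(modules, `[[`, "", "seed"))
  modules[ord2]
}

# 2-core of the module: iteratively drop members with < 2 in-module edges
haircut_2core <- function(adj, members) {
  repeat {
    in_mod <- logical(length(adj))
    in_mod[members] <- TRUE
    deg_in <- vapply(members, function(v) sum(in_mod[adj[[v]]]), 0L)
    if (all(deg_in >= 2L) || length(members) == 0) return(members)
    members <- members[deg_in >= 2L]
  }
}

# fluff stage: append boundary neighbours whose closed-neighbourhood
# density exceeds the threshold (no recursion, per the original tool)
fluff_members <- function(adj, members, fluff_density) {
  in_mod <- logical(length(adj))
  in_mod[members] <- TRUE
  boundary <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                      members)
  add <- boundary[vapply(boundary, function(v) {
    closed <- c(v, adj[[v]])
    m <- length(closed)
    if (m < 2) return(FALSE)
    e <- count_edges_among(adj, closed)
    2 * e / (m * (m - 1)) > fluff_density
  }, TRUE)]
  c(members, add)
}

#' Serialise modules to JSON
#'
#' @param modules List of `module_result` objects.
#' @param path Output path for a JSON array with fields `nodes`,
#'   `n_edges`, `density`, `score`, `seed` per module.
#' @return Invisibly, `path`.
#' @export
write_modules_json <- function(modules, path) {
  payload <- lapply(modules, function(m) {
    list(nodes = m$nodes, n = m$n, n_edges = m$n_edges,
         density = m$density, score = m$score, seed = m$seed)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
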