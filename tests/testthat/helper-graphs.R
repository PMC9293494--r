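# Shared graph constructors and independent oracles for the test suite.

complete_graph <- function(n, ids = NULL) {
  if (is.null(ids)) ids <- paste0("V", seq_len(n))
  interaction_graph(nodes = ids, edges = t(combn(ids, 2)))
}

path_graph <- function(ids) {
  interaction_graph(nodes = ids,
                    edges = cbind(ids[-length(ids)], ids[-1]))
}

star_graph <- function(n_leaves, center = "C0") {
  leaves <- paste0("L", seq_len(n_leaves))
  interaction_graph(nodes = c(center, leaves),
                    edges = cbind(center, leaves))
}

# Erdos-Renyi G(n, p) over letter ids; may be disconnected, never has
# loops or multi-edges.
random_graph <- function(n, p = 0.4) {
  ids <- paste0("N", sprintf("%02d", seq_len(n)))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  interaction_graph(nodes = ids, edges = pairs[keep, , drop = FALSE])
}

adj_matrix <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) {
    A[g$edges] <- 1
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

# all-pairs shortest paths by matrix Floyd-Warshall (independent of the
# BFS code under test)
floyd_warshall <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

oracle_closeness <- function(g) {
  D <- floyd_warshall(g)
  vapply(seq_len(nrow(D)), function(v) {
    reach <- which(is.finite(D[v, ]) & seq_len(ncol(D)) != v)
    if (length(reach) == 0) 0 else length(reach) / sum(D[v, reach])
  }, 0)
}

# betweenness by exhaustive enumeration of all shortest paths (DFS over
# the distance structure); only usable on tiny graphs
oracle_betweenness <- function(g) {
  D <- floyd_warshall(g)
  A <- adj_matrix(g)
  n <- nrow(A)
  enumerate_paths <- function(s, t) {
    # returns list of all shortest s-t paths as integer vectors
    if (!is.finite(D[s, t])) return(list())
    if (s == t) return(list(s))
    out <- list()
    for (w in which(A[, t] > 0)) {
      if (D[s, w] == D[s, t] - 1) {
        for (p in enumerate_paths(s, w)) out <- c(out, list(c(p, t)))
      }
    }
    out
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- enumerate_paths(s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(paths)
      }
    }
  }
  bc
}

oracle_eigenvector <- function(g) {
  A <- adj_matrix(g)
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, which.max(es$values)]
  # Perron vector of the dominant component, made nonnegative
  if (sum(v) < 0) v <- -v
  abs_v <- abs(v)
  abs_v / sqrt(sum(abs_v^2))
}

oracle_lac <- function(g) {
  A <- adj_matrix(g)
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    2 * (sum(A[nb, nb, drop = FALSE]) / 2) / length(nb)
  }, 0)
}

oracle_nc <- function(g) {
  A <- adj_matrix(g)
  deg <- rowSums(A)
  n <- nrow(A)
  nc <- numeric(n)
  for (v in seq_len(n)) {
    for (u in which(A[v, ] > 0)) {
      denom <- min(deg[u], deg[v]) - 1
      if (denom <= 0) next
      z <- sum(A[v, ] * A[u, ])
      nc[v] <- nc[v] + z / denom
    }
  }
  nc
}

# independent above-mean AND-rule, straight off the definition
oracle_key_nodes <- function(g) {
  vals <- cbind(dc = unname(degree_centrality(g)),
                cc = oracle_closeness(g),
                bc = oracle_betweenness(g),
                ec = oracle_eigenvector(g),
                lac = oracle_lac(g),
                nc = oracle_nc(g))
  means <- colMeans(vals)
  g$nodes[apply(vals > rep(means, each = nrow(vals)), 1, all)]
}
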