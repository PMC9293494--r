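test_that("closed-form families: star, path, triangle, complete graph", {
  k4 <- complete_graph(4)
  expect_equal(unname(degree_centrality(k4)), rep(3, 4))
  expect_equal(unname(closeness_centrality(k4)), rep(1, 4))
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  expect_equal(as.numeric(eigenvector_centrality(k4)), rep(0.5, 4),
               tolerance = 1e-9)
  expect_equal(unname(local_average_connectivity(k4)), rep(2, 4))
  expect_equal(unname(network_centrality(k4)), rep(3, 4))

  p3 <- path_graph(c("A", "B", "C"))
  expect_equal(unname(closeness_centrality(p3)), c(2 / 3, 1, 2 / 3))
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))
  expect_equal(as.numeric(eigenvector_centrality(p3)),
               c(0.5, sqrt(2) / 2, 0.5), tolerance = 1e-9)

  s4 <- star_graph(4)
  expect_equal(unname(betweenness_centrality(s4)), c(6, 0, 0, 0, 0))
  expect_equal(unname(local_average_connectivity(s4)), rep(0, 5))
  expect_equal(unname(network_centrality(s4)), rep(0, 5))

  tri <- complete_graph(3)
  m <- attr(centrality_table(tri), "means")
  expect_equal(unname(m[c("dc", "cc", "bc", "lac", "nc")]),
               c(2, 1, 0, 1, 2))
  expect_equal(unname(m["ec"]), 1 / sqrt(3), tolerance = 1e-9)

  ms <- attr(centrality_table(s4), "means")
  expect_equal(unname(ms["dc"]), 1.6)
  expect_equal(unname(ms["bc"]), 1.2)
})

test_that("all six measures match independent oracles on random graphs", {
  set.seed(101)
  n_checked <- 0
  while (n_checked < 60) {
    g <- random_graph(sample(4:8, 1), runif(1, 0.25, 0.8))
    if (graph_size(g) == 0) next
    n_checked <- n_checked + 1
    expect_equal(unname(closeness_centrality(g)), oracle_closeness(g),
                 tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(g),
                 tolerance = 1e-9)
    expect_equal(unname(local_average_connectivity(g)), oracle_lac(g),
                 tolerance = 1e-12)
    expect_equal(unname(network_centrality(g)), oracle_nc(g),
                 tolerance = 1e-12)
    ig <- as_igraph(g)
    expect_equal(unname(degree_centrality(g)),
                 as.numeric(igraph::degree(ig)))
    if (igraph::is_connected(ig)) {
      # unique dominant eigenvalue guaranteed: compare to dense eigensolver
      expect_equal(as.numeric(eigenvector_centrality(g)),
                   oracle_eigenvector(g), tolerance = 1e-8)
      # and to igraph's implementation (L2-rescaled)
      ig_ec <- igraph::eigen_centrality(ig)$vector
      expect_equal(as.numeric(eigenvector_centrality(g)),
                   unname(ig_ec / sqrt(sum(ig_ec^2))), tolerance = 1e-6)
    }
    expect_equal(unname(betweenness_centrality(g)),
                 unname(igraph::betweenness(ig)), tolerance = 1e-9)
  }
})

test_that("measures are invariant under node relabeling", {
  set.seed(55)
  g <- random_graph(8, 0.5)
  perm <- sample(g$nodes)
  relabel <- setNames(paste0("R", seq_along(perm)), perm)
  g2 <- interaction_graph(nodes = unname(relabel[g$nodes]),
                          edges = cbind(relabel[g$edges[, 1]],
                                        relabel[g$edges[, 2]]))
  for (f in list(degree_centrality, closeness_centrality,
                 betweenness_centrality, local_average_connectivity,
                 network_centrality)) {
    v1 <- f(g)
    v2 <- f(g2)
    expect_equal(unname(v2[relabel[g$nodes]]), unname(v1[g$nodes]),
                 tolerance = 1e-12)
  }
  e1 <- eigenvector_centrality(g)
  e2 <- eigenvector_centrality(g2)
  expect_equal(unname(e2[relabel[g$nodes]]), unname(e1[g$nodes]),
               tolerance = 1e-8)
})

test_that("eigenvector centrality validates input and is L2-normalized", {
  expect_error(eigenvector_centrality(interaction_graph(nodes = c("A", "B"))),
               "at least one edge")
  set.seed(9)
  g <- random_graph(7, 0.4)
  ec <- eigenvector_centrality(g)
  expect_equal(sum(ec^2), 1, tolerance = 1e-9)
  expect_true(all(ec >= 0))
  expect_true(attr(ec, "converged"))
})

test_that("vertex-transitive graphs yield empty strict key sets", {
  k5 <- complete_graph(5)
  scr <- screen_key_nodes(centrality_table(k5), k5, strict = TRUE)
  expect_length(scr$key_nodes, 0)
  expect_equal(graph_order(scr$central), 0)

  s4 <- star_graph(4)
  scr_s <- screen_key_nodes(centrality_table(s4), s4, strict = TRUE)
  # all LAC values are 0, so nothing strictly exceeds the LAC mean
  expect_length(scr_s$key_nodes, 0)

  # with >= instead of >, every K5 node passes every test
  lax <- screen_key_nodes(centrality_table(k5), k5, strict = FALSE)
  expect_setequal(lax$key_nodes, k5$nodes)
})

test_that("key-node screen equals an independent re-implementation", {
  set.seed(202)
  n_checked <- 0
  while (n_checked < 25) {
    g <- random_graph(sample(5:8, 1), runif(1, 0.3, 0.7))
    if (graph_size(g) == 0 || !igraph::is_connected(as_igraph(g))) next
    n_checked <- n_checked + 1
    scr <- screen_key_nodes(centrality_table(g), g)
    expect_setequal(scr$key_nodes, oracle_key_nodes(g))
    expect_true(all(scr$key_nodes %in% g$nodes))
    expect_true(all(edge_keys(scr$central) %in% edge_keys(g)))
  }
})

test_that("the screen is scale-invariant per measure", {
  set.seed(77)
  g <- random_graph(8, 0.5)
  tab <- centrality_table(g)
  scaled <- tab
  scales <- c(dc = 3, cc = 10, bc = 0.5, ec = 7, lac = 2, nc = 0.1)
  for (m in names(scales)) scaled[[m]] <- scaled[[m]] * scales[[m]]
  attr(scaled, "means") <- attr(tab, "means") * scales
  expect_identical(screen_key_nodes(scaled, g)$key_nodes,
                   screen_key_nodes(tab, g)$key_nodes)
})

test_that("key nodes are ordered by degree then id", {
  set.seed(88)
  g <- random_graph(8, 0.7)
  scr <- screen_key_nodes(centrality_table(g), g, strict = FALSE)
  deg <- graph_degree(g)[scr$key_nodes]
  expect_true(all(diff(deg) <= 0))
})
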