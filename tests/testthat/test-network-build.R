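test_that("compound-target network is bipartite with hand-countable size", {
  active <- data.frame(mol_id = c("M1", "M2", "M3"),
                       name = c("a", "b", "c"),
                       ob = 50, dl = 0.5, is_active = TRUE,
                       stringsAsFactors = FALSE)
  assoc <- data.frame(
    mol_id = c("M1", "M1", "M2", "M2", "M9"),
    gene = c("SHARED", "ONLY1", "SHARED", "ONLY2", "GHOST"),
    source = "t", stringsAsFactors = FALSE
  )
  res <- build_compound_target_network(active, assoc)
  expect_equal(graph_order(res$graph), 5)   # 2 compounds + 3 genes
  expect_equal(graph_size(res$graph), 4)
  expect_equal(res$n_dropped_assoc, 1)      # M9 not active
  expect_equal(res$compounds_without_targets, "M3")
  # no same-kind edges
  kinds <- res$graph$node_kind
  expect_true(all(kinds[res$graph$edges[, 1]] != kinds[res$graph$edges[, 2]]))
})

test_that("edge counts equal a brute-force pair dedup on random inputs", {
  set.seed(21)
  for (i in 1:10) {
    active <- data.frame(mol_id = paste0("M", 1:6), name = "x",
                         ob = 50, dl = 0.5, stringsAsFactors = FALSE)
    assoc <- data.frame(
      mol_id = sample(paste0("M", 1:8), 60, replace = TRUE),
      gene = sample(paste0("T", 1:12), 60, replace = TRUE),
      stringsAsFactors = FALSE
    )
    res <- build_compound_target_network(active, assoc)
    valid <- assoc[assoc$mol_id %in% active$mol_id, ]
    expect_equal(graph_size(res$graph),
                 nrow(unique(valid[c("mol_id", "gene")])))
  }
})

test_that("degree ranking sorts by degree then id, matching a recount", {
  active <- data.frame(mol_id = c("M1", "M2"), name = "x", ob = 50, dl = 0.5,
                       stringsAsFactors = FALSE)
  assoc <- data.frame(mol_id = c(rep("M1", 5), rep("M2", 2)),
                      gene = c(paste0("A", 1:5), paste0("B", 1:2)),
                      stringsAsFactors = FALSE)
  g <- build_compound_target_network(active, assoc)$graph
  rk <- degree_ranking(g, "compound")
  expect_equal(rk$id, c("M1", "M2"))
  expect_equal(rk$degree, c(5L, 2L))
  rkg <- degree_ranking(g, "gene")
  expect_true(all(diff(rkg$degree) <= 0))
  # tie-break by id within equal degree
  ties <- rkg[rkg$degree == 1, "id"]
  expect_equal(ties, sort(ties))
  expect_error(degree_ranking(interaction_graph(), "compound"), "node_kind")
})

test_that("induced PPI subgraph keeps only seed-seed background edges", {
  bg <- complete_graph(3, c("A", "B", "C"))
  res <- induced_ppi_subgraph(bg, c("A", "B", "D"))
  expect_setequal(res$graph$nodes, c("A", "B"))
  expect_equal(edge_keys(res$graph), "A|B")
  expect_equal(res$absent, "D")

  # no mutual edges + drop_isolated -> empty graph
  bg2 <- interaction_graph(edges = cbind(c("A", "C"), c("B", "D")))
  res2 <- induced_ppi_subgraph(bg2, c("A", "D"), drop_isolated = TRUE)
  expect_equal(graph_order(res2$graph), 0)
  res3 <- induced_ppi_subgraph(bg2, c("A", "D"), drop_isolated = FALSE)
  expect_setequal(res3$graph$nodes, c("A", "D"))

  expect_error(induced_ppi_subgraph(bg, character(0)), "empty seed")
})

test_that("induction equals a brute-force edge filter; identity at full set", {
  set.seed(33)
  for (i in 1:10) {
    bg <- random_graph(10, 0.3)
    seeds <- sample(c(bg$nodes, paste0("X", 1:3)), sample(3:10, 1))
    res <- induced_ppi_subgraph(bg, seeds, drop_isolated = FALSE)
    keep <- bg$edges[, 1] %in% seeds & bg$edges[, 2] %in% seeds
    expect_setequal(edge_keys(res$graph),
                    paste(bg$edges[keep, 1], bg$edges[keep, 2], sep = "|"))
    expect_setequal(res$graph$nodes, intersect(seeds, bg$nodes))
  }
  g <- random_graph(8, 0.5)
  idem <- induced_ppi_subgraph(g, g$nodes, drop_isolated = FALSE)
  expect_setequal(idem$graph$nodes, g$nodes)
  expect_setequal(edge_keys(idem$graph), edge_keys(g))
})

test_that("merged network labels provenance and respects seed union", {
  bg <- interaction_graph(edges = cbind(c("A", "B", "S"), c("B", "S", "A")))
  res <- merge_target_networks(c("A", "S"), c("B", "S"), bg)
  expect_equal(unname(res$provenance[c("A", "B", "S")]),
               c("compound", "disease", "shared"))
  expect_true(all(res$graph$nodes %in% union(c("A", "S"), c("B", "S"))))

  disjoint <- merge_target_networks("A", "B",
                                    interaction_graph(edges = cbind("A", "B")))
  expect_equal(unname(disjoint$provenance[c("A", "B")]),
               c("compound", "disease"))
  expect_error(merge_target_networks(character(0), "B", bg), "non-empty")
})

test_that("shared targets is the exact, symmetric intersection", {
  ct <- c("ESR1", "MAPK14", "CASP3", "AKR1B1", "PTGS2")
  dz <- c("ESR1", "MAPK14", "CASP3", "AKR1B1", "CRYAB")
  expect_equal(shared_targets(ct, dz),
               c("AKR1B1", "CASP3", "ESR1", "MAPK14"))
  expect_equal(shared_targets(ct, dz), shared_targets(dz, ct))
  expect_length(shared_targets(c("A", "B"), c("C", "D")), 0)
})
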