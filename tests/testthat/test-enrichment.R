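# exact combinatorial tail for M small enough that choose() is exact
# integer arithmetic in doubles (C(40, k) < 2^53)
exact_tail <- function(k, n, K, M) {
  i <- seq.int(k, min(n, K))
  if (k == 0) return(1)
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}

test_that("hypergeometric tail: boundary cases and exact values", {
  expect_identical(hypergeometric_tail(0, 5, 5, 10), 1)
  expect_equal(hypergeometric_tail(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_error(hypergeometric_tail(6, 5, 5, 10), "invalid")
  expect_error(hypergeometric_tail(2, 5, 11, 10), "invalid")
})

test_that("hypergeometric tail matches exact oracle and phyper", {
  set.seed(71)
  for (i in 1:120) {
    M <- sample(10:40, 1)
    K <- sample(1:M, 1)
    n <- sample(1:M, 1)
    k <- sample(0:min(n, K), 1)
    p <- hypergeometric_tail(k, n, K, M)
    expect_equal(p, exact_tail(k, n, K, M), tolerance = 1e-10)
  }
  # larger, genome-scale counts against the stats implementation
  for (i in 1:50) {
    M <- sample(1000:20000, 1)
    K <- sample(5:500, 1)
    n <- sample(5:400, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeometric_tail(k, n, K, M),
                 stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("tail is monotone decreasing in the overlap", {
  set.seed(72)
  for (i in 1:20) {
    M <- sample(20:200, 1)
    K <- sample(2:M, 1)
    n <- sample(2:M, 1)
    ks <- 0:min(n, K)
    p <- vapply(ks, function(k) hypergeometric_tail(k, n, K, M), 0)
    expect_true(all(diff(p) <= 1e-12))
  }
})

make_collection <- function(terms, universe = NULL) {
  structure(list(terms = terms,
                 descriptions = setNames(rep("d", length(terms)),
                                         names(terms)),
                 universe = universe),
            class = "annotation_collection")
}

test_that("enrichment ranks a perfectly matching term first", {
  set.seed(73)
  genes <- paste0("G", 1:200)
  planted <- sort(sample(genes, 12))
  terms <- c(list(PLANTED = planted),
             lapply(1:20, function(i) sort(sample(genes, 25))))
  names(terms) <- c("PLANTED", paste0("R", 1:20))
  res <- enrich_gene_set(planted, make_collection(terms))
  expect_equal(res$term_id[1], "PLANTED")
  expect_equal(res$k[1], 12)
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_true(all(res$k <= pmin(res$n, res$K)))
})

test_that("enrichment edge cases: disjoint query, EASE boundary, universe", {
  terms <- list(T1 = c("A", "B", "C"), T2 = c("D", "E"))
  coll <- make_collection(terms)
  # query inside an explicit universe but hitting no term: empty result
  coll_x <- make_collection(terms, universe = c(unlist(terms), "X"))
  expect_equal(nrow(enrich_gene_set("X", coll_x,
                                    universe_mode = "explicit")), 0)
  # a query entirely outside the universe errors instead
  expect_error(enrich_gene_set("A", make_collection(list(T1 = "B"))),
               "universe")

  # EASE with k = 1 tests the tail at 0, so p = 1
  res <- enrich_gene_set("A", coll, ease = TRUE)
  expect_equal(res$p_raw, 1)
  plain <- enrich_gene_set("A", coll, ease = FALSE)
  expect_lt(plain$p_raw, 1)

  # explicit universe changes M
  coll_u <- make_collection(terms, universe = c(unlist(terms), "X", "Y"))
  res_u <- enrich_gene_set(c("A", "B"), coll_u, universe_mode = "explicit")
  expect_equal(res_u$M[1], 7)

  # dropped query genes are counted
  res_d <- enrich_gene_set(c("A", "NOT_ANNOTATED"), coll)
  expect_equal(attr(res_d, "n_dropped"), 1)
})

test_that("EASE is more conservative than the plain tail", {
  set.seed(74)
  genes <- paste0("G", 1:80)
  for (i in 1:15) {
    terms <- list(T = sort(sample(genes, sample(5:30, 1))))
    query <- sample(genes, sample(5:30, 1))
    coll <- make_collection(terms)
    k <- length(intersect(query, terms$T))
    if (k == 0) next
    plain <- enrich_gene_set(query, coll, ease = FALSE)$p_raw
    ease <- enrich_gene_set(query, coll, ease = TRUE)$p_raw
    expect_gte(ease, plain - 1e-15)
  }
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(c(0.5, 0.01), method = "none"), c(0.5, 0.01))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(75)
  p <- runif(30)
  adj <- adjust_pvalues(p)
  expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  expect_equal(order(adj, p), order(p))  # order preserved
  # hand-check the step-up rule on a sorted copy
  ps <- sort(p)
  m <- length(ps)
  hand <- rev(cummin(rev(ps * m / seq_len(m))))
  expect_equal(sort(adj), pmin(hand, 1))
})

test_that("top-term selection filters strictly at alpha then truncates", {
  res <- data.frame(
    term_id = sprintf("T%02d", 1:30),
    p_raw = c(0.05, seq(0.001, 0.028, length.out = 28), 0.9)
  )
  top <- select_top_terms(res, alpha = 0.05, top_k = 20)
  expect_equal(nrow(top), 20)
  expect_false("T01" %in% top$term_id)  # p = 0.05 exactly is excluded
  expect_true(all(diff(top$p_raw) >= 0))
  set.seed(76)
  for (i in 1:10) {
    res <- data.frame(term_id = sprintf("T%02d", 1:25),
                      p_raw = round(runif(25), 2))
    top <- select_top_terms(res, alpha = 0.5, top_k = 7)
    oracle <- res[res$p_raw < 0.5, ]
    oracle <- head(oracle[order(oracle$p_raw, oracle$term_id), ], 7)
    expect_equal(top$term_id, oracle$term_id)
  }
})

test_that("ddCt fold change follows the 2^-ddCt arithmetic", {
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1)
  expect_equal(ddct_fold_change(25, 18, 24, 18), 0.5)
  expect_equal(ddct_fold_change(20, 18, 22, 18), 4)  # ddCt = -2
  # replicates are averaged per group
  expect_equal(ddct_fold_change(c(25, 26), c(18, 18), c(24, 25), c(18, 18)),
               0.5)
  expect_error(ddct_fold_change(NA, 18, 24, 18), "finite")
})
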