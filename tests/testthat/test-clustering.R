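test_that("clique and cycle have the textbook clustering coefficients", {
  k4 <- t(utils::combn(4, 2))
  expect_equal(average_clustering(k4, 4), 1)
  c4 <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  expect_equal(average_clustering(c4, 4), 0)
})

test_that("average clustering equals exhaustive triangle enumeration", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    em <- random_graph(n, runif(1, 0.2, 0.6))
    got <- average_clustering(em, n)
    expect_equal(got, oracle_average_clustering(em, n))
    if (requireNamespace("igraph", quietly = TRUE) && nrow(em) > 0) {
      ig <- igraph::graph_from_edgelist(em, directed = FALSE)
      ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
      cc <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
      cc[is.nan(cc)] <- 0
      expect_equal(got, mean(cc))
    }
  }
})

test_that("enhanced subgraph keeps exactly the over-threshold edges", {
  ref <- reference_stats(2, 0.5)  # enhanced > 3
  g <- make_graph(5, rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5)),
                  widths = c(5, 4, 3.5, 1, 2))
  sub <- enhanced_subgraph(g, ref)
  expect_equal(nrow(sub$edges), 3)
  expect_equal(average_clustering(sub), 3 / 5)  # planted triangle on 1,2,3

  none <- enhanced_subgraph(make_graph(3, rbind(c(1, 2)), widths = 1), ref)
  expect_equal(nrow(none$edges), 0)
  all_e <- enhanced_subgraph(make_graph(3, rbind(c(1, 2), c(2, 3)), widths = c(9, 9)), ref)
  expect_equal(nrow(all_e$edges), 2)
})

test_that("permutation test is deterministic and handles degenerate input", {
  set.seed(55)
  em <- random_graph(7, 0.5)
  g <- make_graph(7, em, widths = runif(nrow(em), 1, 5))
  ref <- reference_stats(2, 0.5)
  r1 <- permutation_test(g, ref, 200, seed = 9)
  r2 <- permutation_test(g, ref, 200, seed = 9)
  expect_identical(r1$permuted_cc, r2$permuted_cc)
  expect_equal(r1$p_score, mean(r1$permuted_cc < r1$observed_cc))
  expect_equal(r1$expected_cc, mean(r1$permuted_cc))

  degen <- permutation_test(make_graph(3, rbind(c(1, 2)), widths = 0.1), ref, 100, 1)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_score))
})

test_that("with every edge enhanced all permutations equal the observed graph", {
  em <- t(utils::combn(5, 2))
  g <- make_graph(5, em, widths = rep(10, nrow(em)))
  res <- permutation_test(g, reference_stats(2, 0.5), 100, seed = 3)
  expect_equal(res$observed_cc, 1)
  expect_equal(res$relative_deviation, 0)
  expect_equal(res$p_score, 0)   # strict inequality: ties are not smaller
})

test_that("expected clustering converges to the exact subset mean", {
  set.seed(77)
  em <- rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(2, 4), c(5, 1))
  w <- c(5, 5, 1, 1, 5, 1, 1)          # k = 3 enhanced of 7 edges
  g <- make_graph(5, em, w)
  ref <- reference_stats(2, 1)         # enhanced > 4
  k <- sum(w > 4)
  subsets <- utils::combn(nrow(em), k)
  exact <- mean(apply(subsets, 2, function(s) {
    average_clustering(em[s, , drop = FALSE], 5)
  }))
  res <- permutation_test(g, ref, 4000, seed = 19)
  expect_lt(abs(res$expected_cc - exact), 0.01)
})

test_that("the null distribution depends only on the edge count of the subgraph", {
  set.seed(88)
  em <- random_graph(10, 0.5)
  w <- runif(nrow(em), 1, 5)
  g1 <- make_graph(10, em, w)
  g2 <- make_graph(10, em, sample(w))   # permuted widths: same multiset
  ref <- reference_stats(1.5, 0.5)
  r1 <- permutation_test(g1, ref, 300, seed = 4)
  r2 <- permutation_test(g2, ref, 300, seed = 4)
  expect_identical(r1$permuted_cc, r2$permuted_cc)
})

test_that("observed clustering is invariant to node relabelling", {
  set.seed(66)
  em <- random_graph(9, 0.4)
  w <- runif(nrow(em), 1, 6)
  ref <- reference_stats(2, 0.5)
  perm <- sample(9)
  em2 <- cbind(perm[em[, 1]], perm[em[, 2]])
  r1 <- permutation_test(make_graph(9, em, w), ref, 50, seed = 2)
  r2 <- permutation_test(make_graph(9, em2, w), ref, 50, seed = 2)
  expect_equal(r1$observed_cc, r2$observed_cc)
})
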