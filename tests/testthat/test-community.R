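test_that("similarity graph construction averages directed confusion mass", {
  cm <- matrix(c(0.8, 0.2, 0.6, 0.4), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  g <- build_similarity_graph(cm)
  # cm[A,B] = 0.6, cm[B,A] = 0.2 -> weight 0.4; diagonal discarded
  expect_equal(g$weights["A", "B"], 0.4)
  expect_equal(diag(g$weights), c(A = 0, B = 0))
  # identity confusion -> all-zero edges
  id <- diag(3); dimnames(id) <- list(LETTERS[1:3], LETTERS[1:3])
  expect_true(all(build_similarity_graph(id)$weights == 0))
  # rectangular matrices embed on the label union
  rect <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2,
                 dimnames = list(c("D1-a", "D1-b"), c("D2-a", "D2-b")))
  gr <- build_similarity_graph(rect)
  expect_setequal(gr$nodes, c("D1-a", "D1-b", "D2-a", "D2-b"))
  expect_equal(gr$weights["D1-a", "D2-a"], 0.45)
})

test_that("modularity matches the defining formula and igraph's oracle", {
  g <- two_triangle_graph()
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 2), g$nodes)
  expect_equal(modularity(g, memb), 0.5)
  # all nodes in one community -> 0 for any graph
  expect_equal(modularity(g, stats::setNames(rep(1, 6), g$nodes)), 0)
  # independent oracle: igraph on random weighted graphs
  skip_if_not_installed("igraph")
  withr::local_seed(5)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- round(runif(n * (n - 1) / 2) *
                               rbinom(n * (n - 1) / 2, 1, 0.6), 3)
    w <- w + t(w)
    rownames(w) <- colnames(w) <- paste0("v", 1:n)
    if (sum(w) == 0) next
    g2 <- similarity_graph(w)
    memb2 <- stats::setNames(sample(1:3, n, replace = TRUE), g2$nodes)
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(modularity(g2, memb2),
                 igraph::modularity(ig, memb2[igraph::V(ig)$name],
                                    weights = igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
  expect_error(modularity(g, memb[1:3]), "invalid-partition")
})

test_that("louvain solves planted two-clique graphs to the brute-force optimum", {
  for (sz in list(c(2, 2), c(2, 3), c(3, 3), c(2, 4))) {
    for (bridge in c(0, 0.1)) {
      g <- two_clique_graph(sz[1], sz[2], bridge)
      part <- louvain(g, seed = 1)
      expect_equal(part$modularity, brute_force_best_modularity(g),
                   tolerance = 1e-12)
      # the planted split is recovered
      truth <- rep(1:2, c(sz[1], sz[2]))
      expect_equal(length(unique(part$membership[truth == 1])), 1L)
      expect_equal(length(unique(part$membership[truth == 2])), 1L)
    }
  }
})

test_that("two disjoint triangles give exactly two communities at Q = 0.5", {
  part <- louvain(two_triangle_graph(), seed = 3)
  expect_equal(part$n_communities, 2L)
  expect_equal(part$modularity, 0.5)
  m <- part$membership
  expect_equal(unname(m[c("n1", "n2", "n3")]), rep(m[["n1"]], 3))
  expect_equal(unname(m[c("n4", "n5", "n6")]), rep(m[["n4"]], 3))
})

test_that("complete uniform graphs collapse to one community with Q = 0", {
  w <- matrix(1, 6, 6); diag(w) <- 0
  part <- louvain(similarity_graph(w), seed = 2)
  expect_equal(part$n_communities, 1L)
  expect_equal(part$modularity, 0)
  # brute force agrees that nothing beats Q = 0 here
  expect_equal(brute_force_best_modularity(similarity_graph(w)), 0,
               tolerance = 1e-12)
})

test_that("louvain's reported Q equals independently recomputed modularity", {
  withr::local_seed(11)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2) * rbinom(n * (n - 1) / 2, 1, 0.5)
    w <- w + t(w)
    rownames(w) <- colnames(w) <- paste0("v", 1:n)
    g <- similarity_graph(w)
    part <- louvain(g, seed = i)
    expect_equal(part$modularity, modularity(g, part$membership),
                 tolerance = 1e-12)
    # near-optimality on small graphs: at least 95% of partitions are no better
    qs <- vapply(all_partitions(n), function(p) {
      modularity(g, stats::setNames(p, g$nodes))
    }, numeric(1))
    expect_gte(mean(part$modularity >= qs - 1e-12), 0.95)
  }
})

test_that("louvain is deterministic given a seed and flags edgeless graphs", {
  g <- two_clique_graph(3, 3, bridge = 0.2)
  p1 <- louvain(g, seed = 42)
  p2 <- louvain(g, seed = 42)
  expect_identical(p1$membership, p2$membership)
  z <- louvain(similarity_graph(matrix(0, 4, 4)))
  expect_true(z$degenerate)
  expect_equal(z$n_communities, 4L)
  expect_equal(z$modularity, 0)
})

test_that("graph exports write the declared formats", {
  g <- two_clique_graph(2, 2, bridge = 0.3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(g, f1)
  el <- read.csv(f1)
  expect_equal(sort(names(el)), c("from", "to", "weight"))
  expect_equal(nrow(el), 3L)  # 2 intra + 1 bridge
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, f2)
  txt <- readLines(f2)
  expect_true(any(grepl("graphml", txt)))
  skip_if_not_installed("igraph")
  ig <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::gorder(ig), 4)
  expect_equal(igraph::gsize(ig), 3)
})
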