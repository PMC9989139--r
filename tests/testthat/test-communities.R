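test_that("modularity matches hand values and the double-sum oracle", {
  A <- two_triangles()
  expect_equal(modularity_value(A, c(1, 1, 1, 2, 2, 2)), 0.5)
  # all nodes in one community -> 0 for any graph
  set.seed(21)
  for (s in 1:5) {
    G <- random_graph(12, 0.4, 100 + s)
    if (sum(G) == 0) next
    expect_equal(modularity_value(G, rep(1, 12)), 0, tolerance = 1e-12)
    labs <- sample(1:4, 12, replace = TRUE)
    expect_equal(modularity_value(G, labs, gamma = 1.3),
                 oracle_modularity(G, labs, 1.3), tolerance = 1e-12)
  }
  expect_error(modularity_value(matrix(0, 3, 3), c(1, 1, 2)), "empty graph")
  expect_error(modularity_value(matrix(c(0, 1, 0, 0), 2, 2), c(1, 2)),
               "symmetric")
})

test_that("Louvain recovers exact optima on canonical graphs", {
  A <- two_triangles()
  lab <- louvain_partition(A, gamma = 1, seed = 1)
  expect_equal(lab[1], lab[2]); expect_equal(lab[2], lab[3])
  expect_equal(lab[4], lab[5]); expect_equal(lab[5], lab[6])
  expect_false(lab[1] == lab[4])
  K6 <- 1 - diag(6)
  expect_equal(length(unique(louvain_partition(K6, 1, 1))), 1)
  expect_error(louvain_partition(matrix(c(0, 1, 0, 0), 2, 2), 1, 1),
               "symmetric")
})

test_that("Louvain never scores below the trivial partitions it refines", {
  for (s in 1:5) {
    G <- random_graph(20, 0.25, 300 + s)
    if (sum(G) == 0) next
    lab <- louvain_partition(G, 1, seed = s)
    expect_gte(modularity_value(G, lab), modularity_value(G, rep(1, 20)) - 1e-12)
  }
})

test_that("consensus has unit stability on an unambiguous optimum", {
  A <- two_triangles()
  cp <- consensus_partition(A, gamma = 1, n_iter = 50, seed = 2)
  expect_equal(cp$stability, rep(1, 6))
  expect_equal(cp$modularity, 0.5)
  # allegiance matrix is block-diagonal 1/0
  P_expect <- matrix(0, 6, 6)
  P_expect[1:3, 1:3] <- 1; P_expect[4:6, 4:6] <- 1
  expect_equal(cp$allegiance, P_expect)
})

test_that("consensus is invariant to node relabelling", {
  g <- planted_block_graph(5, n_per_block = 5)
  cp1 <- consensus_partition(g$A, 1, n_iter = 30, seed = 9)
  perm <- sample(seq_len(30))
  cp2 <- consensus_partition(g$A[perm, perm], 1, n_iter = 30, seed = 9)
  # same partition structure after undoing the permutation
  undo <- integer(30); undo[perm] <- seq_len(30)
  same1 <- outer(cp1$labels, cp1$labels, "==")
  same2 <- outer(cp2$labels[undo], cp2$labels[undo], "==")
  expect_gte(mean(same1 == same2), 0.95)
})

test_that("label matching is stable and permutation-coherent", {
  lab <- c(1L, 1L, 2L, 2L, 3L, 3L)
  expect_identical(match_labels(lab, lab), lab)
  relab <- c(3L, 3L, 1L, 1L, 2L, 2L)   # same partition, renamed
  expect_identical(match_labels(relab, lab), lab)
})

test_that("resolution sweep has the documented default grid and drives community count", {
  expect_length(seq(1, 2.5, by = 0.05), 31)   # default gamma grid
  A <- two_triangles()
  sw <- sweep_parameters(A, gammas = c(0.5, 1, 3, 6, 12), n_iter = 20, seed = 3)
  expect_equal(nrow(sw), 5)
  # n_communities non-decreasing in gamma on this graph
  expect_true(all(diff(sw$n_communities) >= 0))
  sw1 <- sweep_parameters(A, gammas = 1, n_iter = 10, seed = 3)
  expect_equal(nrow(sw1), 1)
  expect_equal(select_gamma(sw, target_n = 2), 0.5)
})

test_that("dynamic assignment is constant across identical uncoupled layers", {
  A <- two_triangles()
  mats <- list(L1 = A, L2 = A, L3 = A)
  da <- dynamic_assignment(mats, gamma = 1, omega = 0, n_iter = 20, seed = 4)
  expect_equal(node_flexibility(da$Q)$mean, 0)
  expect_error(dynamic_assignment(list(A), 1, 0, 10), "2 layers")
  expect_error(dynamic_assignment(list(A, A[1:5, 1:5]), 1, 0, 10),
               "node set")
})

test_that("dynamic assignment recovers a planted block switch", {
  # 60-node 6-block layers; 10 nodes move to a different block at layer 3
  g1 <- planted_block_graph(71)
  blocks2 <- g1$blocks
  movers <- c(1:5, 11:15)
  blocks2[movers] <- c(rep(3, 5), rep(4, 5))
  set.seed(72)
  A2 <- matrix(0L, 60, 60)
  for (i in 1:59) for (j in (i + 1):60) {
    p <- if (blocks2[i] == blocks2[j]) 0.6 else 0.05
    A2[i, j] <- A2[j, i] <- rbinom(1, 1, p)
  }
  mats <- list(L1 = g1$A, L2 = g1$A, L3 = A2, L4 = A2)
  da <- dynamic_assignment(mats, gamma = 1, omega = 0.5, n_iter = 30, seed = 6)
  fl <- node_flexibility(da$Q)$f
  # movers change assignment at the switch, stayers mostly do not
  expect_gte(sum(fl[movers] > 0), 9)
  expect_lt(mean(fl[-movers]), 0.1)
})

test_that("stronger coupling smooths assignments (flexibility non-increasing)", {
  set.seed(73)
  mats <- lapply(1:4, function(l) {
    g <- planted_block_graph(80 + l, n_per_block = 5)
    g$A
  })
  names(mats) <- paste0("L", 1:4)
  fl <- vapply(c(0, 0.5, 5), function(om) {
    da <- dynamic_assignment(mats, gamma = 1, omega = om, n_iter = 25, seed = 7)
    node_flexibility(da$Q)$mean
  }, numeric(1))
  expect_true(all(diff(fl) <= 1e-9))
})

test_that("community naming picks the best-overlap reference network", {
  labels <- c(rep(1, 4), rep(2, 4))
  reference <- list(front = 1:4, back = 5:8)
  nm <- name_communities(labels, reference)
  expect_equal(nm$best_match, c("front", "back"))
  expect_equal(nm$jaccard, c(1, 1))
})
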