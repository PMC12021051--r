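test_that("energy score reproduces closed-form values", {
  expect_equal(energy_score(matrix(2.5, 1, 1)), -2.5)
  expect_equal(energy_score(matrix(0, 1, 2)), -log(2))
  expect_equal(energy_score(matrix(1:3, 1)), -log(sum(exp(1:3))))
  expect_equal(round(energy_score(matrix(1:3, 1)), 4), -3.4076)
})

test_that("energy matches a direct exp-sum-log oracle and never overflows", {
  set.seed(13)
  for (i in 1:100) {
    l <- matrix(runif(12, -30, 30), 3, 4)
    expect_equal(energy_score(l), -log(rowSums(exp(l))), tolerance = 1e-9)
  }
  big <- matrix(c(1e4, 1e4 - 1, -1e4, 0), 2, 2)
  expect_true(all(is.finite(energy_score(big))))
  # shifting all logits of a node by c shifts its energy by exactly -c
  l <- matrix(rnorm(8), 2, 4)
  expect_equal(energy_score(l + 5), energy_score(l) - 5)
})

test_that("propagation matrix is row-stochastic on the two-hop support", {
  B <- propagation_matrix(path3())
  expect_equal(as.numeric(B[1, ]), c(0, 0.5, 0.5))  # b 1-hop, c 2-hop
  expect_equal(as.numeric(B[2, ]), c(0.5, 0, 0.5))
  Bt <- propagation_matrix(triangle())
  expect_equal(Matrix::diag(Bt), rep(0, 3))
  expect_equal(as.numeric(Bt[1, ]), c(0, 0.5, 0.5))
  g <- cell_graph(3, rbind(c(1, 2)))  # node 3 isolated
  B3 <- propagation_matrix(g)
  expect_equal(as.numeric(B3[3, ]), c(0, 0, 1))
  set.seed(5)
  for (i in 1:10) {
    gr <- random_graph(15, 0.2)
    expect_equal(Matrix::rowSums(propagation_matrix(gr)), rep(1, 15),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("propagation algebra: fixed point, constants, hand example", {
  B <- propagation_matrix(triangle())
  e0 <- c(0, 1, 4)
  expect_equal(propagate_energy(e0, B, beta = 1, K = 7), e0)
  expect_equal(propagate_energy(rep(3.3, 3), B, beta = 0.2, K = 5),
               rep(3.3, 3))
  two <- propagation_matrix(cell_graph(2, rbind(c(1, 2))))
  expect_equal(propagate_energy(c(0, 1), two, beta = 0.5, K = 1),
               c(0.5, 0.5))
  expect_equal(propagate_energy(c(0, 1), two, beta = 0.5, K = 0), c(0, 1))
})

test_that("propagated energies stay within the initial range and contract", {
  set.seed(31)
  n_done <- 0
  while (n_done < 20) {
    g <- random_graph(12, 0.35)
    if (any(graph_degree(g) == 0)) next
    ig <- igraph::graph_from_adjacency_matrix(
      as.matrix(adjacency_matrix(g)), mode = "undirected")
    if (!igraph::is_connected(ig)) next
    n_done <- n_done + 1
    B <- propagation_matrix(g)
    e0 <- rnorm(12, sd = 3)
    spread <- Inf
    for (K in 0:6) {
      eK <- propagate_energy(e0, B, beta = runif(1), K = K)
      expect_gte(min(eK), min(e0) - 1e-12)
      expect_lte(max(eK), max(e0) + 1e-12)
    }
    # with beta < 1 the spread is non-increasing in K
    for (beta in c(0.3, 0.7)) {
      prev <- diff(range(propagate_energy(e0, B, beta, 0)))
      for (K in 1:6) {
        cur <- diff(range(propagate_energy(e0, B, beta, K)))
        expect_lte(cur, prev + 1e-12)
        prev <- cur
      }
    }
  }
})

test_that("threshold calibration follows the inverse-ECDF rule", {
  expect_equal(calibrate_threshold(1:100, 0.95), 5)
  expect_equal(calibrate_threshold(rep(2.5, 30), 0.95), 2.5)
  expect_equal(calibrate_threshold(1:99, 0.5), 50)  # type-1 median
  expect_error(calibrate_threshold(1:10, 0.95), ">= 20")
  # the declared property: >= tpr_target of known cells sit above threshold
  set.seed(3)
  s <- rnorm(200)
  thr <- calibrate_threshold(s, 0.95)
  expect_gte(mean(s >= thr), 0.95)
})

test_that("detect_novel composes the pieces and is equivariant", {
  set.seed(17)
  logits <- matrix(rnorm(60), 20, 3)
  g <- random_graph(20, 0.25)
  res <- detect_novel(logits, g, beta = 0.6, K = 2, threshold = -1e9)
  expect_equal(res$score, -res$energyK)
  expect_false(any(res$is_novel))  # permissive threshold -> no calls
  # beta = 1: propagation is the identity
  res1 <- detect_novel(logits, g, beta = 1, K = 5)
  expect_equal(res1$energyK, res1$energy0)
  # permuting nodes permutes scores
  perm <- sample(20)
  gp <- cell_graph(20, cbind(match(g$edges[, 1], perm),
                             match(g$edges[, 2], perm)))
  resp <- detect_novel(logits[perm, ], gp, beta = 0.6, K = 2)
  expect_equal(resp$score, res$score[perm], tolerance = 1e-12)
})

test_that("an unconfident node carries the top propagated energy locally", {
  # star of 4 nodes: node 1 center; node 4 has near-zero logit mass
  g <- cell_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  logits <- rbind(c(5, 0), c(5, 0), c(5, 0), c(-50, -50))
  res <- detect_novel(logits, g, beta = 0.5, K = 1)
  expect_equal(which.max(res$energyK), 4L)
  expect_equal(which.min(res$score), 4L)
})
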