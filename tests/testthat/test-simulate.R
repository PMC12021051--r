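test_that("simulation is reproducible and respects config invariants", {
  cfg <- synth_config(n_cells = 50, n_genes = 40, n_types = 3,
                      markers_per_type = 5, seed = 13)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(as.matrix(s1$dataset$counts), as.matrix(s2$dataset$counts))
  expect_identical(s1$truth$labels, s2$truth$labels)
  expect_equal(s1$truth$novel_mask, s1$truth$labels == 1)
  expect_error(synth_config(n_genes = 10, n_types = 4,
                            markers_per_type = 5), "exceeds")
  expect_error(synth_config(n_types = 1), "n_types")
  expect_error(synth_config(n_types = 5, two_hop_signal = TRUE),
               "n_types = 4")
})

test_that("large-dispersion, no-dropout counts approach the Poisson limit", {
  cfg <- synth_config(n_cells = 4000, n_genes = 60, n_types = 2,
                      markers_per_type = 10, theta = 1e6, pi0 = 0,
                      novel_type_index = NULL, seed = 17)
  sim <- simulate_counts(cfg)
  x <- as.matrix(sim$dataset$counts)
  # variance ~ mean per gene *within a type* (between-type program
  # differences would otherwise inflate the variance); the sample variance
  # of a variance estimate at n = 2000 per type has ~3% relative sd, so the
  # bulk must sit very close and no gene may stray far
  rel <- unlist(lapply(1:2, function(t) {
    xt <- x[sim$truth$labels == t, ]
    m <- colMeans(xt)
    v <- apply(xt, 2, var)
    abs(v - m) / m
  }))
  expect_lt(median(rel), 0.05)
  expect_lt(max(rel), 0.15)
})

test_that("per-gene moments match the ZINB analytics within 3 SE", {
  cfg <- synth_config(n_cells = 2000, n_genes = 50, n_types = 2,
                      markers_per_type = 8, theta = 2, pi0 = 0.3,
                      novel_type_index = NULL, seed = 19)
  sim <- simulate_counts(cfg)
  x <- as.matrix(sim$dataset$counts)
  mu <- sim$truth$mu
  pi0 <- 0.3; th <- 2
  # mean: E[X] = (1 - pi) mu; zero fraction: P(0) = pi + (1-pi)(th/(th+mu))^th
  # Family-level check over the gene battery: typical gene well within 3 SE,
  # only a sampling-consistent few beyond, none far out.
  z <- unlist(lapply(seq_len(ncol(x)), function(j) {
    m_exp <- mean((1 - pi0) * mu[, j])
    v_entries <- (1 - pi0) * (mu[, j] + mu[, j]^2 / th) +
      pi0 * (1 - pi0) * mu[, j]^2
    p0 <- pi0 + (1 - pi0) * (th / (th + mu[, j]))^th
    c(abs(mean(x[, j]) - m_exp) / (sqrt(sum(v_entries)) / nrow(x)),
      abs(mean(x[, j] == 0) - mean(p0)) /
        (sqrt(sum(p0 * (1 - p0))) / nrow(x)))
  }))
  expect_lt(mean(z), 1.5)
  expect_lte(mean(z > 3), 0.02)
  expect_lt(max(z), 5)
})

test_that("zero fraction under dropout stays in (pi0, 1) for mu >= 1", {
  cfg <- synth_config(n_cells = 1500, n_genes = 30, n_types = 2,
                      markers_per_type = 5, pi0 = 0.5, base_mu = 1,
                      novel_type_index = NULL, seed = 23)
  x <- as.matrix(simulate_counts(cfg)$dataset$counts)
  zf <- colMeans(x == 0)
  # every gene's zero fraction sits at or above the inflation floor (up to
  # binomial noise) and strictly below 1
  se <- sqrt(0.5 * 0.5 / nrow(x))
  expect_true(all(zf >= 0.5 - 3 * se))
  expect_gte(mean(zf), 0.5)
  expect_true(all(zf < 1))
})

test_that("edge homophily decreases as mixing grows (3-seed average)", {
  means <- sapply(c(0, 0.4, 0.8), function(mix) {
    mean(sapply(c(1, 2, 3), function(s) {
      cfg <- synth_config(n_cells = 400, mixing = mix, seed = s)
      homophily_of_simulation(cfg, k = 15)$edge_homophily
    }))
  })
  expect_true(all(diff(means) < 0))
  expect_gte(means[1], 0.9)  # well-separated programs are homophilous
})

test_that("the two-hop generator hides labels from one-hop views", {
  cfg <- synth_config(n_cells = 200, n_genes = 80, n_types = 4,
                      markers_per_type = 10, two_hop_signal = TRUE,
                      novel_type_index = NULL, seed = 29)
  sim <- simulate_counts(cfg)
  g <- sim$truth$planted_graph
  expect_s3_class(g, "CellGraph")
  types <- sim$truth$labels
  prog <- heterocell:::type_programs(cfg)
  # identity types share a program; relay types share another
  expect_equal(prog[1, ], prog[2, ])
  expect_equal(prog[3, ], prog[4, ])
  # identity cells have exactly one (unique) relay neighbor
  idx <- two_hop_neighborhoods(g)
  for (t in 1:2) {
    nbs <- idx$one_hop[types == t]
    expect_true(all(lengths(nbs) == 1))
    expect_true(all(types[unlist(nbs)] == t + 2))
    expect_false(any(duplicated(unlist(nbs))))
  }
  # two-hop views differ: type 1 sees relays, type 2 sees nothing
  th1 <- idx$two_hop[types == 1]
  th2 <- idx$two_hop[types == 2]
  expect_true(all(lengths(th1) > 0))
  expect_true(all(types[unlist(th1)] == 3))
  expect_true(all(lengths(th2) == 0))
})
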