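test_that("cross-entropy reproduces hand-derived values", {
  # near-perfect prediction
  l <- matrix(c(1000, 0, 0), 1)
  expect_lt(cross_entropy_loss(l, 1L), 1e-6)
  # uniform over 4 classes
  expect_equal(cross_entropy_loss(matrix(0, 1, 4), 2L), log(4))
  # single node, logits (1,2,3), true class 3
  val <- -log(exp(3) / sum(exp(1:3)))
  expect_equal(cross_entropy_loss(matrix(1:3, 1), 3L), val)
  expect_equal(round(val, 4), 0.4076)
})

test_that("cross-entropy is shift-invariant and masked correctly", {
  set.seed(1)
  logits <- matrix(rnorm(20), 5, 4)
  y <- sample(4, 5, replace = TRUE)
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  base <- cross_entropy_loss(logits, y, mask)
  expect_equal(cross_entropy_loss(logits + 7, y, mask), base)
  # masked-out nodes do not contribute
  logits2 <- logits
  logits2[3, ] <- 1e6
  expect_equal(cross_entropy_loss(logits2, y, mask), base)
  expect_error(cross_entropy_loss(logits, y, rep(FALSE, 5)), "no nodes")
  # huge logits stay finite (log-sum-exp)
  expect_true(is.finite(cross_entropy_loss(matrix(c(1e4, 0), 1), 1L)))
})

test_that("ZINB NLL reproduces hand-derived point values", {
  # point mass at zero
  expect_equal(zinb_nll(0, pi = 1, mu = 1, theta = 1), 0)
  # x=0, pi=.5, mu=1, theta=1: pmf = .5 + .5 * .5 = .75
  expect_equal(zinb_nll(0, 0.5, 1, 1), -log(0.75))
  expect_equal(round(zinb_nll(0, 0.5, 1, 1), 4), 0.2877)
  # x=1, pi=0 reduces to NB: pmf = .25
  expect_equal(zinb_nll(1, 0, 1, 1), -log(0.25))
  expect_equal(round(zinb_nll(1, 0, 1, 1), 4), 1.3863)
  expect_error(zinb_nll(1, NaN, 1, 1), "non-finite")
  expect_error(zinb_nll(-1, 0.1, 1, 1), "non-negative")
})

test_that("ZINB NLL matches the direct-pmf oracle on a dense grid", {
  grid <- expand.grid(x = 0:10, pi = c(0, 0.3, 0.9), mu = c(0.1, 1, 10),
                      theta = c(0.5, 1, 10))
  ours <- with(grid, zinb_nll_matrixfree <- mapply(
    function(x, p, m, t) zinb_nll(x, p, m, t), x, pi, mu, theta))
  reference <- with(grid, mapply(
    function(x, p, m, t) oracle_zinb_nll(x, p, m, t), x, pi, mu, theta))
  expect_equal(ours, reference, tolerance = 1e-6)
})

test_that("ZINB limits: NB at pi -> 0, Poisson at large theta", {
  x <- rep(0:10, times = 3)
  mu <- rep(c(0.5, 2, 8), each = 11)
  nb <- -mean(dnbinom(x, size = 1.7, mu = mu, log = TRUE))
  expect_equal(zinb_nll(x, 1e-12, mu, 1.7), nb, tolerance = 1e-6)
  pois <- -mean(dpois(x, mu, log = TRUE))
  expect_equal(zinb_nll(x, 0, mu, 1e6), pois, tolerance = 1e-3)
})

test_that("compiled ZINB kernel agrees with the reference implementation", {
  set.seed(21)
  n <- 400
  x <- matrix(rnbinom(n, size = 1.5, mu = 4) *
                rbinom(n, 1, 0.7), 20)
  ppi <- matrix(rnorm(n), 20)
  pmu <- matrix(rnorm(n, 1, 2), 20)
  pth <- matrix(rnorm(n, 0, 2), 20)
  pi <- plogis(pmin(pmax(ppi, qlogis(1e-6)), qlogis(1 - 1e-6)))
  mu <- exp(pmin(pmax(pmu, log(1e-5)), log(1e6)))
  th <- exp(pmin(pmax(pth, log(1e-5)), log(1e6)))
  kern <- heterocell:::zinb_loss_grad_cpp(x, ppi, pmu, pth)
  ref <- heterocell:::zinb_loss_and_pregrad(x, pi, mu, th)
  expect_equal(kern$nll, ref$nll, tolerance = 1e-12)
  expect_equal(kern$d_ppi, ref$d_ppi, tolerance = 1e-10)
  expect_equal(kern$d_pmu, ref$d_pmu, tolerance = 1e-10)
  expect_equal(kern$d_pth, ref$d_pth, tolerance = 1e-10)
  expect_equal(kern$nll, zinb_nll(x, pi, mu, th), tolerance = 1e-12)
})

test_that("total loss is the alpha-weighted sum", {
  expect_equal(total_loss(1.3, 99, alpha = 0), 1.3)
  expect_equal(total_loss(1, 2, 1e-4), 1.0002)
  a1 <- 0.3; a2 <- 0.8; lz <- 2.5
  expect_equal(total_loss(1, lz, a1) + total_loss(1, lz, a2) - 2,
               (a1 + a2) * lz)
})

test_that("with alpha = 0 the decoder heads receive zero gradient", {
  sim <- quick_sim(n_cells = 15, n_genes = 12, n_types = 3, seed = 2)
  ds <- sim$ds
  g <- build_knn_graph(ds, k = 2)
  sp <- make_splits(ds, 0.2, 0.2, novel_class = NULL, seed = 1)
  enc <- encoder_config(in_dim = n_genes(ds), n_classes = 3, seed = 1)
  st <- init_model(enc, n_genes(ds))
  idx <- two_hop_neighborhoods(g)
  y <- match(ds$labels, sort(unique(ds$labels)))
  fw <- heterocell:::model_forward(st, ds$normalized, idx, decode = TRUE)
  gr <- heterocell:::model_backward(st, fw, ds$normalized,
                                    as.matrix(ds$counts), y, sp$train_mask,
                                    alpha = 0, idx)
  for (nm in c("Wpi", "Wmu", "Wth", "Wd", "bpi", "bmu", "bth", "bd")) {
    expect_true(all(gr[[nm]] == 0), label = nm)
  }
  expect_false(all(gr$Wc == 0))
})
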