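small_config <- function(...) {
  encoder_config(in_dim = 6, n_classes = 3, extract_dim = 4, hidden_dim = 4,
                 decoder_hidden = 4, ...)
}

test_that("initialization is seed-deterministic with consistent shapes", {
  cfg <- small_config(seed = 5)
  s1 <- init_model(cfg, n_genes = 6)
  s2 <- init_model(cfg, n_genes = 6)
  expect_identical(s1$params, s2$params)
  s3 <- init_model(small_config(seed = 6), n_genes = 6)
  expect_false(identical(s1$params, s3$params))
  expect_equal(dim(s1$params$We), c(6, 4))
  expect_equal(dim(s1$params$gl1.W2), c(4, 4))
  expect_equal(dim(s1$params$Wc), c(8, 3))  # extract + 1 graph layer
  expect_equal(dim(s1$params$Wpi), c(4, 6))
})

test_that("graph layer computes self + one-hop + two-hop sums", {
  idx <- two_hop_neighborhoods(path3())
  h <- matrix(c(1, 2, 3), 3, 1)
  I1 <- matrix(1, 1, 1)
  # W0=W1=W2=1, identity activation: a gets 1+2+3, b gets 2+(1+3)+0, c sym.
  out <- graph_layer_forward(h, idx, I1, I1, I1, activation = "identity")
  expect_equal(as.numeric(out), c(6, 6, 6))
  # W1=W2=0, W0=I, ReLU on non-negative input is the identity
  Z0 <- matrix(0, 1, 1)
  expect_equal(graph_layer_forward(h, idx, I1, Z0, Z0), h)
  expect_equal(graph_layer_forward(h, idx, Z0, Z0, Z0),
               matrix(0, 3, 1))
  expect_error(graph_layer_forward(h, idx, matrix(1, 2, 1), I1, I1),
               "shape")
})

test_that("encoder concatenates cross-layer activations", {
  cfg <- small_config(n_graph_layers = 0)
  st <- init_model(cfg, 6)
  X <- matrix(rnorm(18), 3, 6)
  idx <- two_hop_neighborhoods(path3())
  fw <- encoder_forward(st, X, idx)
  expect_equal(fw$Z, fw$layer_activations[[1]])

  cfg2 <- small_config(n_graph_layers = 2)
  st2 <- init_model(cfg2, 6)
  fw2 <- encoder_forward(st2, X, idx)
  expect_equal(ncol(fw2$Z), 4 + 2 * 4)
  expect_length(fw2$layer_activations, 3)
})

test_that("forward pass is permutation-equivariant", {
  sim <- quick_sim(n_cells = 25, n_genes = 30)$ds
  g <- build_knn_graph(sim, k = 3)
  cfg <- encoder_config(in_dim = n_genes(sim), n_classes = 3, seed = 2)
  st <- init_model(cfg, n_genes(sim))
  idx <- two_hop_neighborhoods(g)
  fw <- encoder_forward(st, sim$normalized, idx)
  set.seed(3)
  perm <- sample(25)
  gp <- cell_graph(25, cbind(match(g$edges[, 1], perm),
                             match(g$edges[, 2], perm)))
  fwp <- encoder_forward(st, sim$normalized[perm, ],
                         two_hop_neighborhoods(gp))
  expect_equal(fwp$Z, fw$Z[perm, ], tolerance = 1e-12)
})

test_that("graph-free weights make predictions graph-independent", {
  sim <- quick_sim(n_cells = 20, n_genes = 30)$ds
  cfg <- encoder_config(in_dim = n_genes(sim), n_classes = 3, seed = 4)
  st <- init_model(cfg, n_genes(sim))
  st$params$gl1.W1[] <- 0
  st$params$gl1.W2[] <- 0
  g1 <- build_knn_graph(sim, k = 2)
  g2 <- cell_graph(20, rbind(c(1, 20), c(5, 6)))
  z1 <- encoder_forward(st, sim$normalized, two_hop_neighborhoods(g1))$Z
  z2 <- encoder_forward(st, sim$normalized, two_hop_neighborhoods(g2))$Z
  expect_equal(z1, z2)
})

test_that("outputs ignore W2 when the graph has no two-hop pairs", {
  g <- triangle()  # complete: nobody is at distance 2
  X <- matrix(rnorm(18), 3, 6)
  cfg <- small_config(seed = 9)
  st <- init_model(cfg, 6)
  idx <- two_hop_neighborhoods(g)
  z1 <- encoder_forward(st, X, idx)$Z
  st$params$gl1.W2[] <- rnorm(length(st$params$gl1.W2))
  z2 <- encoder_forward(st, X, idx)$Z
  expect_equal(z1, z2)
})

test_that("classifier head is affine without softmax", {
  cfg <- small_config(seed = 1)
  st <- init_model(cfg, 6)
  Z <- matrix(rnorm(24), 3, 8)
  expect_equal(dim(classify(st, Z)), c(3L, 3L))
  st0 <- st
  st0$params$Wc[] <- 0
  st0$params$bc[] <- 0
  expect_equal(classify(st0, Z), matrix(0, 3, 3), ignore_attr = TRUE)
  st1 <- st
  st1$params$bc[2] <- st1$params$bc[2] + 3
  expect_equal(classify(st1, Z)[, 2], classify(st, Z)[, 2] + 3)
  expect_equal(classify(st1, Z)[, 1], classify(st, Z)[, 1])
})

test_that("ZINB heads respect their link ranges and zero-weight values", {
  cfg <- small_config(seed = 3)
  st <- init_model(cfg, 6)
  for (nm in c("Wd", "bd", "Wpi", "bpi", "Wmu", "bmu", "Wth", "bth")) {
    st$params[[nm]][] <- 0
  }
  Z <- matrix(rnorm(24), 3, 8)
  dec <- zinb_decode(st, Z)
  expect_true(all(dec$pi == 0.5))
  expect_true(all(dec$mu == 1))
  expect_true(all(dec$theta == 1))

  st2 <- init_model(cfg, 6)
  wild <- zinb_decode(st2, Z * 10)
  expect_true(all(wild$pi > 0 & wild$pi < 1))
  expect_true(all(wild$mu > 0))
  expect_true(all(wild$theta > 0))

  # exponential link: doubling the mu pre-activations squares M
  dec2 <- zinb_decode(st2, Z)
  st3 <- st2
  st3$params$Wmu <- st3$params$Wmu * 2
  st3$params$bmu <- st3$params$bmu * 2
  dec3 <- zinb_decode(st3, Z)
  unclamped <- dec2$mu > 1e-5 & dec2$mu < 1e6 & dec3$mu > 1e-5 &
    dec3$mu < 1e6
  expect_equal(dec3$mu[unclamped], dec2$mu[unclamped]^2, tolerance = 1e-10)
})

test_that("checkpoints reload bit-exactly", {
  st <- init_model(small_config(seed = 8), 6)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, f)
  expect_identical(load_checkpoint(f), st)
})

test_that("analytic gradients match finite differences", {
  sim <- quick_sim(n_cells = 15, n_genes = 12, n_types = 3, seed = 6)
  ds <- sim$ds
  g <- build_knn_graph(ds, k = 2)
  sp <- make_splits(ds, 0.2, 0.2, novel_class = NULL, seed = 1)
  enc <- encoder_config(in_dim = n_genes(ds), n_classes = 3, extract_dim = 5,
                        hidden_dim = 4, decoder_hidden = 4,
                        activation = "tanh", seed = 2)
  idx <- two_hop_neighborhoods(g)
  st <- init_model(enc, n_genes(ds))
  X <- ds$normalized
  counts <- as.matrix(ds$counts)
  y <- match(ds$labels, sort(unique(ds$labels)))
  alpha <- 0.05
  loss_at <- function(params) {
    s <- st; s$params <- params
    fw <- heterocell:::model_forward(s, X, idx, decode = TRUE)
    lc <- cross_entropy_loss(fw$logits, y, sp$train_mask)
    lz <- heterocell:::zinb_loss_grad_cpp(counts, fw$ppi, fw$pmu, fw$pth)$nll
    lc + alpha * lz
  }
  fw <- heterocell:::model_forward(st, X, idx, decode = TRUE)
  grads <- heterocell:::model_backward(st, fw, X, counts, y, sp$train_mask,
                                       alpha, idx)
  eps <- 1e-5
  set.seed(11)
  for (nm in c("We", "gl1.W0", "gl1.W1", "gl1.W2", "Wc", "bc", "Wd",
               "Wpi", "Wmu", "Wth", "bth", "be")) {
    for (j in sample(length(st$params[[nm]]), 3)) {
      up <- st$params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- st$params; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(grads[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
})
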