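#' Encoder configuration
#'
#' Architecture of the heterophily-aware encoder: an initial per-cell feature
#' extraction layer (MLP, width `extract_dim`), `n_graph_layers` graph layers
#' of width `hidden_dim` performing two-hop message passing with separate
#' weight matrices for the self term, one-hop sum and two-hop sum, a linear
#' classifier head on the cross-layer concatenated embedding, and a ZINB
#' decoder (one hidden layer of width `decoder_hidden`) producing per-gene
#' dropout, mean and dispersion.
#'
#' @param in_dim number of input genes (after HVG selection).
#' @param n_classes number of known cell types (>= 2).
#' @param extract_dim width of the extraction layer (default 32).
#' @param hidden_dim graph-layer width (default 32).
#' @param n_graph_layers number of graph layers (default 1).
#' @param activation `"relu"` (default), `"tanh"` or `"identity"`.
#' @param bias include bias terms in all affine maps (default `TRUE`; set
#'   `FALSE` to keep the literal bias-free message-passing equations).
#' @param mean_aggregate normalize neighbor sums by neighborhood size
#'   (default `FALSE`: plain sums).
#' @param two_hop include the two-hop aggregation term (default `TRUE`;
#'   `FALSE` is the one-hop-only ablation: the `W2` term is dropped from
#'   every layer).
#' @param decoder_hidden width of the decoder trunk (default `hidden_dim`).
#' @param seed integer seed for weight initialization.
#' @return An object of class `EncoderConfig`.
#' @export
encoder_config <- function(in_dim, n_classes, extract_dim = 32,
                           hidden_dim = 32, n_graph_layers = 1,
                           activation = c("relu", "tanh", "identity"),
                           bias = TRUE, mean_aggregate = FALSE,
                           two_hop = TRUE,
                           decoder_hidden = hidden_dim, seed = 42) {
  activation <- match.arg(activation)
  stopifnot(in_dim >= 1, extract_dim >= 1, hidden_dim >= 1,
            n_graph_layers >= 0, n_classes >= 2, decoder_hidden >= 1)
  structure(list(in_dim = as.integer(in_dim),
                 n_classes = as.integer(n_classes),
                 extract_dim = as.integer(extract_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_graph_layers = as.integer(n_graph_layers),
                 activation = activation, bias = bias,
                 mean_aggregate = mean_aggregate, two_hop = two_hop,
                 decoder_hidden = as.integer(decoder_hidden),
                 seed = as.integer(seed)),
            class = "EncoderConfig")
}

## Embedding width after cross-layer concatenation.
embedding_dim <- function(config) {
  config$extract_dim + config$n_graph_layers * config$hidden_dim
}

activation_fun <- function(name) {
  switch(name,
         relu = list(f = function(x) pmax(x, 0),
                     grad = function(pre, post) pre > 0),
         tanh = list(f = tanh,
                     grad = function(pre, post) 1 - post^2),
         identity = list(f = identity,
                         grad = function(pre, post) 1))
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialize model weights
#'
#' All affine maps are initialized with fan-scaled (Glorot uniform) draws from
#' a generator seeded by `config$seed`; biases start at zero. Two calls with
#' the same configuration give bitwise-identical states.
#'
#' @param config an [encoder_config()].
#' @param n_genes number of genes reconstructed by the ZINB decoder.
#' @param mean_deg1,mean_deg2 mean one-hop / two-hop neighborhood sizes of
#'   the graph the model will run on. The message passing uses unnormalized
#'   neighbor sums, so the effective fan-in of `W1`/`W2` is the input width
#'   times the neighborhood size; their initial scale is shrunk by
#'   `sqrt(mean_deg)` to keep initial activations O(1) (defaults 1 = plain
#'   fan-scaled init).
#' @return An object of class `ModelState`: list with `config`, `n_genes` and
#'   `params`, a flat named list of weight matrices / bias vectors
#'   (`We`, `be`, `gl<l>.W0/W1/W2/b`, `Wc`, `bc`, `Wd`, `bd`,
#'   `Wpi/Wmu/Wth` + biases).
#' @export
init_model <- function(config, n_genes, mean_deg1 = 1, mean_deg2 = 1) {
  stopifnot(inherits(config, "EncoderConfig"), n_genes >= 1,
            mean_deg1 >= 0, mean_deg2 >= 0)
  d0 <- config$extract_dim
  dh <- config$hidden_dim
  dd <- config$decoder_hidden
  zdim <- embedding_dim(config)
  s1 <- 1 / sqrt(max(mean_deg1, 1))
  s2 <- 1 / sqrt(max(mean_deg2, 1))
  params <- with_seed(config$seed, {
    p <- list(We = glorot(config$in_dim, d0), be = numeric(d0))
    din <- d0
    for (l in seq_len(config$n_graph_layers)) {
      p[[paste0("gl", l, ".W0")]] <- glorot(din, dh)
      p[[paste0("gl", l, ".W1")]] <- glorot(din, dh) * s1
      p[[paste0("gl", l, ".W2")]] <- glorot(din, dh) * s2
      p[[paste0("gl", l, ".b")]] <- numeric(dh)
      din <- dh
    }
    p$Wc <- glorot(zdim, config$n_classes)
    p$bc <- numeric(config$n_classes)
    p$Wd <- glorot(zdim, dd)
    p$bd <- numeric(dd)
    p$Wpi <- glorot(dd, n_genes); p$bpi <- numeric(n_genes)
    p$Wmu <- glorot(dd, n_genes); p$bmu <- numeric(n_genes)
    p$Wth <- glorot(dd, n_genes); p$bth <- numeric(n_genes)
    p
  })
  structure(list(config = config, n_genes = as.integer(n_genes),
                 params = params),
            class = "ModelState")
}

#' @export
print.ModelState <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("ModelState: ", x$config$in_dim, " genes -> extract ",
      x$config$extract_dim, " -> ", x$config$n_graph_layers,
      " graph layer(s) x ", x$config$hidden_dim, " -> ",
      x$config$n_classes, " classes | ZINB decoder over ", x$n_genes,
      " genes | ", np, " parameters\n", sep = "")
  invisible(x)
}

add_bias <- function(M, b, use_bias = TRUE) {
  if (!use_bias) return(M)
  M + matrix(b, nrow(M), length(b), byrow = TRUE)
}

#' One graph layer of two-hop message passing
#'
#' Computes, for every node i,
#' `activation(W0 h_i + W1 * sum over one-hop h_j + W2 * sum over two-hop
#' h_k (+ b))`. Empty neighborhoods contribute zero vectors.
#'
#' @param h_prev nodes x width input activations.
#' @param index a [two_hop_neighborhoods()] index.
#' @param W0,W1,W2 weight matrices (input width x output width).
#' @param b optional bias vector (`NULL` for none).
#' @param activation activation name (see [encoder_config()]).
#' @param mean_aggregate divide neighbor sums by neighborhood sizes.
#' @return nodes x output-width activation matrix.
#' @export
graph_layer_forward <- function(h_prev, index, W0, W1, W2, b = NULL,
                                activation = "relu",
                                mean_aggregate = FALSE) {
  if (ncol(h_prev) != nrow(W0)) stop("shape mismatch: h_prev has ",
                                     ncol(h_prev), " columns, W0 expects ",
                                     nrow(W0), call. = FALSE)
  act <- activation_fun(activation)
  s1 <- as.matrix(index$A1 %*% h_prev)
  s2 <- as.matrix(index$A2 %*% h_prev)
  if (mean_aggregate) {
    s1 <- s1 / pmax(Matrix::rowSums(index$A1), 1)
    s2 <- s2 / pmax(Matrix::rowSums(index$A2), 1)
  }
  pre <- h_prev %*% W0 + s1 %*% W1 + s2 %*% W2
  if (!is.null(b)) pre <- add_bias(pre, b)
  act$f(pre)
}

## Full forward pass with caches for backprop. Returns activations, the
## cross-layer embedding Z, logits and (optionally) ZINB parameters.
model_forward <- function(state, X, index, decode = TRUE) {
  cfg <- state$config
  p <- state$params
  act <- activation_fun(cfg$activation)
  pre <- list()
  H <- list()
  pre[[1]] <- add_bias(X %*% p$We, p$be, cfg$bias)
  H[[1]] <- act$f(pre[[1]])
  S1 <- list(); S2 <- list()
  d1 <- pmax(Matrix::rowSums(index$A1), 1)
  d2 <- pmax(Matrix::rowSums(index$A2), 1)
  use2 <- is.null(cfg$two_hop) || cfg$two_hop
  for (l in seq_len(cfg$n_graph_layers)) {
    h_in <- H[[l]]
    s1 <- as.matrix(index$A1 %*% h_in)
    s2 <- if (use2) as.matrix(index$A2 %*% h_in) else
      matrix(0, nrow(h_in), ncol(h_in))
    if (cfg$mean_aggregate) { s1 <- s1 / d1; if (use2) s2 <- s2 / d2 }
    S1[[l]] <- s1; S2[[l]] <- s2
    pr <- h_in %*% p[[paste0("gl", l, ".W0")]] +
      s1 %*% p[[paste0("gl", l, ".W1")]] +
      s2 %*% p[[paste0("gl", l, ".W2")]]
    pr <- add_bias(pr, p[[paste0("gl", l, ".b")]],
                   use_bias = cfg$bias)
    pre[[l + 1]] <- pr
    H[[l + 1]] <- act$f(pr)
  }
  Z <- do.call(cbind, H)
  logits <- add_bias(Z %*% p$Wc, p$bc, cfg$bias)
  out <- list(H = H, pre = pre, S1 = S1, S2 = S2, Z = Z, logits = logits)
  if (decode) out <- c(out, zinb_heads(state, Z, links = FALSE))
  out
}

## Numerically safe link ranges for the ZINB heads. Pre-activations are
## clamped before the link so out-of-range values carry zero gradient.
.PI_CLAMP <- stats::qlogis(c(1e-6, 1 - 1e-6))
.LOG_CLAMP <- log(c(1e-5, 1e6))

zinb_heads <- function(state, Z, links = TRUE) {
  cfg <- state$config
  p <- state$params
  act <- activation_fun(cfg$activation)
  preD <- add_bias(Z %*% p$Wd, p$bd, cfg$bias)
  D <- act$f(preD)
  out <- list(preD = preD, D = D,
              ppi = add_bias(D %*% p$Wpi, p$bpi, cfg$bias),
              pmu = add_bias(D %*% p$Wmu, p$bmu, cfg$bias),
              pth = add_bias(D %*% p$Wth, p$bth, cfg$bias))
  if (links) {
    ppi_c <- pmin(pmax(out$ppi, .PI_CLAMP[1]), .PI_CLAMP[2])
    pmu_c <- pmin(pmax(out$pmu, .LOG_CLAMP[1]), .LOG_CLAMP[2])
    pth_c <- pmin(pmax(out$pth, .LOG_CLAMP[1]), .LOG_CLAMP[2])
    out$pi <- 1 / (1 + exp(-ppi_c))
    out$mu <- exp(pmu_c)
    out$theta <- exp(pth_c)
  }
  out
}

#' Encoder forward pass
#'
#' Runs the extraction layer and all graph layers, returning the per-layer
#' activations and the cross-layer concatenated embedding `Z`.
#'
#' @param state a [init_model()] state.
#' @param X_norm cells x genes normalized feature matrix (width =
#'   `config$in_dim`).
#' @param index a [two_hop_neighborhoods()] index for the cell graph.
#' @return List with `layer_activations` (list of per-node matrices,
#'   `h^(0)..h^(L)`) and `Z` (nodes x embedding_dim).
#' @export
encoder_forward <- function(state, X_norm, index) {
  if (ncol(X_norm) != state$config$in_dim) {
    stop("X_norm has ", ncol(X_norm), " columns; encoder expects ",
         state$config$in_dim, call. = FALSE)
  }
  fw <- model_forward(state, as.matrix(X_norm), index, decode = FALSE)
  list(layer_activations = fw$H, Z = fw$Z)
}

#' Classifier head
#'
#' Affine map of the embedding to per-class logits; no softmax is applied
#' (the softmax lives in the loss and in prediction).
#'
#' @param state a [init_model()] state.
#' @param Z nodes x embedding_dim matrix from [encoder_forward()].
#' @return nodes x n_classes logit matrix.
#' @export
classify <- function(state, Z) {
  add_bias(Z %*% state$params$Wc, state$params$bc, state$config$bias)
}

#' ZINB decoder heads
#'
#' Maps the embedding through the decoder trunk and the three heads:
#' dropout probability via a logistic link, mean and dispersion via
#' exponential links, each clamped to numerically safe ranges
#' (`pi` in `[1e-6, 1-1e-6]`, `mu`/`theta` in `[1e-5, 1e6]`).
#'
#' @inheritParams classify
#' @return List with matrices `pi`, `mu`, `theta` (nodes x n_genes).
#' @export
zinb_decode <- function(state, Z) {
  h <- zinb_heads(state, Z, links = TRUE)
  list(pi = h$pi, mu = h$mu, theta = h$theta)
}

#' Save / load a model checkpoint
#'
#' Single-file container holding the configuration and every weight array;
#' reloads bit-exactly.
#'
#' @param state a `ModelState`.
#' @param path file path (`.rds`).
#' @return `path` (save) or the restored `ModelState` (load).
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "ModelState"))
  state
}
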