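#' Training configuration
#'
#' Default protocol: 200 epochs of full-batch Adam with
#' learning rate 1e-2, weight decay 5e-3 and ZINB weight `alpha_zinb = 1e-4`.
#'
#' @param epochs number of epochs (>= 0).
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to every parameter gradient.
#' @param alpha_zinb weight of the ZINB reconstruction term in the total loss.
#' @param seed integer seed (weight init and any stochastic components).
#' @param selection `"best"` returns the weights of the epoch with highest
#'   validation accuracy (ties -> earliest epoch); `"final"` returns the last
#'   epoch.
#' @param eval_every evaluate validation accuracy every this many epochs.
#' @param grad_clip optional global gradient-norm clip (e.g. 5); `NULL` off.
#' @return An object of class `TrainConfig`.
#' @export
train_config <- function(epochs = 200, learning_rate = 1e-2,
                         weight_decay = 5e-3, alpha_zinb = 1e-4, seed = 42,
                         selection = c("best", "final"), eval_every = 1,
                         grad_clip = NULL) {
  selection <- match.arg(selection)
  stopifnot(epochs >= 0, learning_rate > 0, weight_decay >= 0,
            alpha_zinb >= 0, eval_every >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, alpha_zinb = alpha_zinb,
                 seed = as.integer(seed), selection = selection,
                 eval_every = as.integer(eval_every), grad_clip = grad_clip),
            class = "TrainConfig")
}

## Full backward pass. Returns the gradient of
## L = cross_entropy(train nodes) + alpha * mean ZINB NLL (all nodes x genes)
## for every parameter, as a named list shaped like state$params.
model_backward <- function(state, fw, X, counts, labels, train_mask, alpha,
                           index, zinb_pregrad = NULL) {
  cfg <- state$config
  p <- state$params
  act <- activation_fun(cfg$activation)
  n <- nrow(X)
  g <- list()

  dlogits <- cross_entropy_grad(fw$logits, labels, train_mask)
  g$Wc <- crossprod(fw$Z, dlogits)
  g$bc <- colSums(dlogits)
  dZ <- tcrossprod(dlogits, p$Wc)

  if (alpha > 0) {
    scale <- alpha / (n * state$n_genes)
    pg <- if (is.null(zinb_pregrad))
      zinb_loss_grad_cpp(counts, fw$ppi, fw$pmu, fw$pth) else zinb_pregrad
    Gpi <- pg$d_ppi * scale
    Gmu <- pg$d_pmu * scale
    Gth <- pg$d_pth * scale
    g$Wpi <- crossprod(fw$D, Gpi); g$bpi <- colSums(Gpi)
    g$Wmu <- crossprod(fw$D, Gmu); g$bmu <- colSums(Gmu)
    g$Wth <- crossprod(fw$D, Gth); g$bth <- colSums(Gth)
    dD <- tcrossprod(Gpi, p$Wpi) + tcrossprod(Gmu, p$Wmu) +
      tcrossprod(Gth, p$Wth)
    GD <- dD * act$grad(fw$preD, fw$D)
    g$Wd <- crossprod(fw$Z, GD); g$bd <- colSums(GD)
    dZ <- dZ + tcrossprod(GD, p$Wd)
  } else {
    zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
      else numeric(length(x))
    for (nm in c("Wpi", "bpi", "Wmu", "bmu", "Wth", "bth", "Wd", "bd")) {
      g[[nm]] <- zero_like(p[[nm]])
    }
  }

  # split dZ back into per-layer blocks of the concatenation
  widths <- c(cfg$extract_dim, rep(cfg$hidden_dim, cfg$n_graph_layers))
  ends <- cumsum(widths)
  starts <- c(1, utils::head(ends, -1) + 1)
  dH <- lapply(seq_along(widths), function(l)
    dZ[, starts[l]:ends[l], drop = FALSE])

  d1 <- pmax(Matrix::rowSums(index$A1), 1)
  d2 <- pmax(Matrix::rowSums(index$A2), 1)
  use2 <- is.null(cfg$two_hop) || cfg$two_hop
  for (l in rev(seq_len(cfg$n_graph_layers))) {
    G <- dH[[l + 1]] * act$grad(fw$pre[[l + 1]], fw$H[[l + 1]])
    g[[paste0("gl", l, ".W0")]] <- crossprod(fw$H[[l]], G)
    g[[paste0("gl", l, ".W1")]] <- crossprod(fw$S1[[l]], G)
    g[[paste0("gl", l, ".W2")]] <- crossprod(fw$S2[[l]], G)
    g[[paste0("gl", l, ".b")]] <- colSums(G)
    t1 <- tcrossprod(G, p[[paste0("gl", l, ".W1")]])
    if (cfg$mean_aggregate) t1 <- t1 / d1
    back <- tcrossprod(G, p[[paste0("gl", l, ".W0")]]) +
      as.matrix(index$A1 %*% t1)
    if (use2) {
      t2 <- tcrossprod(G, p[[paste0("gl", l, ".W2")]])
      if (cfg$mean_aggregate) t2 <- t2 / d2
      back <- back + as.matrix(index$A2 %*% t2)
    }
    dH[[l]] <- dH[[l]] + back
  }
  G0 <- dH[[1]] * act$grad(fw$pre[[1]], fw$H[[1]])
  g$We <- crossprod(X, G0)
  g$be <- colSums(G0)

  if (!cfg$bias) {
    for (nm in grep("^b|\\.b$", names(g), value = TRUE)) g[[nm]][] <- 0
  }
  g[names(state$params)]
}

adam_init <- function(params) {
  zero <- lapply(params, function(x)
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train the model on a cell graph
#'
#' Full-batch gradient descent with the Adam update on the total loss: the
#' cross-entropy term is masked to training nodes; the ZINB reconstruction
#' term covers the raw HVG counts of all nodes (reconstruction needs no
#' labels). With `selection = "best"` the returned weights are those of the
#' epoch with highest validation accuracy. Fully deterministic given the
#' seeds.
#'
#' @param ds an [expression_dataset()] with a normalized layer (features) and
#'   raw counts (reconstruction targets).
#' @param graph a [cell_graph()] over the same cells.
#' @param splits a [make_splits()] assignment.
#' @param enc an [encoder_config()]; `NULL` builds the default architecture
#'   for this dataset (seeded from `cfg$seed`).
#' @param cfg a [train_config()].
#' @return An object of class `HeteronetFit`: list with `state` (the selected
#'   `ModelState`), `history` (per-epoch data frame of `l_cls`, `l_zinb`,
#'   `l_total`, `val_acc`), `classes` (known class labels, sorted),
#'   `best_epoch`, `enc`, `cfg`.
#' @export
train_heteronet <- function(ds, graph, splits, enc = NULL,
                            cfg = train_config()) {
  if (is.null(ds$normalized)) {
    stop("dataset has no normalized layer; run normalize_log() first",
         call. = FALSE)
  }
  if (!any(splits$train_mask)) stop("empty training mask", call. = FALSE)
  if (any(splits$novel_mask & (splits$train_mask | splits$val_mask))) {
    stop("novel cells must not carry training labels", call. = FALSE)
  }
  X <- as.matrix(ds$normalized)
  counts <- dense_counts(ds)
  known_mask <- splits$train_mask | splits$val_mask
  classes <- sort(unique(ds$labels[known_mask]))
  if (length(classes) < 2) stop("need >= 2 known classes", call. = FALSE)
  y <- match(ds$labels, classes)  # NA for the withheld class
  if (anyNA(y[splits$train_mask])) {
    stop("novel cells must not carry training labels", call. = FALSE)
  }
  if (is.null(enc)) {
    enc <- encoder_config(in_dim = ncol(X), n_classes = length(classes),
                          seed = cfg$seed)
  }
  index <- two_hop_neighborhoods(graph)
  # under sum aggregation the neighbor terms have effective fan-in deg x din;
  # shrink their init accordingly (mean mode already keeps activations O(1))
  state <- if (enc$mean_aggregate) init_model(enc, n_genes = ncol(counts))
  else init_model(enc, n_genes = ncol(counts),
                  mean_deg1 = mean(Matrix::rowSums(index$A1)),
                  mean_deg2 = mean(Matrix::rowSums(index$A2)))
  opt <- adam_init(state$params)
  has_val <- any(splits$val_mask)
  hist <- vector("list", cfg$epochs)
  best <- list(params = state$params, acc = -Inf, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    fw <- model_forward(state, X, index, decode = cfg$alpha_zinb > 0)
    l_cls <- cross_entropy_loss(fw$logits, y, splits$train_mask)
    pg <- NULL
    l_zinb <- NA_real_
    if (cfg$alpha_zinb > 0) {
      pg <- zinb_loss_grad_cpp(counts, fw$ppi, fw$pmu, fw$pth)
      l_zinb <- pg$nll
    }
    l_tot <- total_loss(l_cls, if (is.na(l_zinb)) 0 else l_zinb,
                        cfg$alpha_zinb)
    if (!is.finite(l_tot)) {
      stop("non-finite training loss at epoch ", ep,
           "; try a smaller learning_rate or enable grad_clip",
           call. = FALSE)
    }
    grads <- model_backward(state, fw, X, counts, y, splits$train_mask,
                            cfg$alpha_zinb, index, zinb_pregrad = pg)
    if (cfg$weight_decay > 0) {
      for (nm in names(grads)) {
        grads[[nm]] <- grads[[nm]] + cfg$weight_decay * state$params[[nm]]
      }
    }
    if (!is.null(cfg$grad_clip)) {
      gnorm <- sqrt(sum(vapply(grads, function(x) sum(x^2), 0)))
      if (gnorm > cfg$grad_clip) {
        grads <- lapply(grads, function(x) x * (cfg$grad_clip / gnorm))
      }
    }
    st <- adam_step(state$params, grads, opt, cfg$learning_rate)
    state$params <- st$params
    opt <- st$opt
    val_acc <- NA_real_
    if (has_val && (ep %% cfg$eval_every == 0 || ep == cfg$epochs)) {
      fw_post <- model_forward(state, X, index, decode = FALSE)
      pred <- max.col(fw_post$logits, ties.method = "first")
      val_acc <- mean(pred[splits$val_mask] == y[splits$val_mask])
      if (val_acc > best$acc) {
        best <- list(params = state$params, acc = val_acc, epoch = ep)
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, l_cls = l_cls, l_zinb = l_zinb,
                             l_total = l_tot, val_acc = val_acc)
  }
  history <- if (cfg$epochs) do.call(rbind, hist) else
    data.frame(epoch = integer(), l_cls = numeric(), l_zinb = numeric(),
               l_total = numeric(), val_acc = numeric())
  if (cfg$selection == "best" && has_val && best$epoch > 0) {
    state$params <- best$params
  }
  structure(list(state = state, history = history, classes = classes,
                 best_epoch = if (has_val) best$epoch else cfg$epochs,
                 enc = enc, cfg = cfg),
            class = "HeteronetFit")
}

#' @export
print.HeteronetFit <- function(x, ...) {
  cat("HeteronetFit: ", length(x$classes), " known classes, ",
      nrow(x$history), " epochs trained", sep = "")
  if (nrow(x$history)) {
    cat(sprintf(" | final l_total %.4f", utils::tail(x$history$l_total, 1)))
    va <- x$history$val_acc[!is.na(x$history$val_acc)]
    if (length(va)) cat(sprintf(" | best val acc %.3f (epoch %d)",
                                max(va), x$best_epoch))
  }
  cat("\n")
  invisible(x)
}

#' Predict cell types (and return logits / embeddings)
#'
#' @param fit a [train_heteronet()] fit.
#' @param ds dataset whose normalized layer feeds the encoder.
#' @param graph the cell graph.
#' @return List with `logits` (cells x classes), `pred` (character labels),
#'   `Z` (embedding), `classes`.
#' @export
predict_heteronet <- function(fit, ds, graph) {
  index <- two_hop_neighborhoods(graph)
  fw <- model_forward(fit$state, as.matrix(ds$normalized), index,
                      decode = FALSE)
  pred_idx <- max.col(fw$logits, ties.method = "first")
  list(logits = fw$logits, pred = fit$classes[pred_idx], Z = fw$Z,
       classes = fit$classes)
}
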