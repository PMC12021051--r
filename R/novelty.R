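#' Energy score of classifier logits
#'
#' `E_i = -log sum_c exp(logits[i, c])`, evaluated with a log-sum-exp so
#' large logits cannot overflow. High energy (low total logit mass) marks a
#' cell unlike every training class.
#'
#' @param logits cells x C matrix of finite logits.
#' @return Numeric vector of per-cell energies.
#' @export
energy_score <- function(logits) {
  logits <- as.matrix(logits)
  -row_logsumexp(logits)
}

#' Two-hop propagation matrix
#'
#' Row-stochastic matrix `B` supported on the union of each node's one-hop
#' and two-hop neighborhoods ("within two hops"); every supported entry of
#' row i equals `1 / |support(i)|`. Isolated nodes receive a self-loop so
#' every row sums to one.
#'
#' @param graph a [cell_graph()].
#' @param normalization `"row"` (default, convex averaging) or `"symmetric"`
#'   (`D^{-1/2} (A1+A2) D^{-1/2}`).
#' @return Sparse `dgCMatrix` of class-attribute `PropagationMatrix`.
#' @export
propagation_matrix <- function(graph, normalization = c("row", "symmetric")) {
  normalization <- match.arg(normalization)
  index <- two_hop_neighborhoods(graph)
  S <- index$A1 + index$A2            # disjoint supports; entries 1
  deg <- Matrix::rowSums(S)
  iso <- which(deg == 0)
  if (length(iso)) {
    S <- S + Matrix::sparseMatrix(i = iso, j = iso, x = 1,
                                  dims = dim(S))
    deg[iso] <- 1
  }
  B <- if (normalization == "row") {
    Matrix::Diagonal(x = 1 / deg) %*% S
  } else {
    Dh <- Matrix::Diagonal(x = 1 / sqrt(deg))
    Dh %*% S %*% Dh
  }
  B <- methods::as(B, "CsparseMatrix")
  attr(B, "normalization") <- normalization
  B
}

#' Propagate energies over the graph
#'
#' K applications of the recurrence `E^k = beta * E^{k-1} + (1 - beta) * B
#' E^{k-1}`, a convex mixing of each cell's own energy with the mean energy
#' of its (within-two-hop) neighborhood.
#'
#' @param energy0 per-node initial energies.
#' @param B a [propagation_matrix()].
#' @param beta own-vs-neighborhood balance in `[0, 1]` (default 0.5).
#' @param K number of propagation steps (>= 0; default 2).
#' @return Per-node energies after K steps.
#' @export
propagate_energy <- function(energy0, B, beta = 0.5, K = 2) {
  stopifnot(beta >= 0, beta <= 1, K >= 0)
  e <- as.numeric(energy0)
  for (k in seq_len(K)) {
    e <- beta * e + (1 - beta) * as.numeric(B %*% e)
  }
  e
}

#' Calibrate the novelty threshold on validation known cells
#'
#' Returns the `(1 - tpr_target)` empirical quantile (inverse-ECDF, i.e.
#' `type = 1`) of the known-cell scores, so that a fraction `tpr_target` of
#' known cells score at or above the threshold.
#'
#' @param scores_known_val novelty scores of >= 20 validation known cells.
#' @param tpr_target target true-positive (known-retention) rate in (0, 1);
#'   default 0.95.
#' @return Scalar threshold; cells scoring strictly below it are called
#'   novel.
#' @export
calibrate_threshold <- function(scores_known_val, tpr_target = 0.95) {
  stopifnot(tpr_target > 0, tpr_target < 1)
  if (length(scores_known_val) < 20) {
    stop("need >= 20 validation known cells to calibrate (got ",
         length(scores_known_val), ")", call. = FALSE)
  }
  # round the probability so 1 - 0.95 does not drift past 0.05 in floating
  # point and shift the inverse-ECDF step
  unname(stats::quantile(scores_known_val,
                         probs = round(1 - tpr_target, 10), type = 1))
}

#' Detect novel cells
#'
#' Composes [energy_score()], [propagation_matrix()] and
#' [propagate_energy()]. The reported novelty score is the negated propagated
#' energy, so that a low score indicates a novel cell; cells scoring strictly
#' below `threshold` are called novel. Detection never modifies the trained
#' model.
#'
#' @param logits cells x C logits from the trained model.
#' @param graph the cell graph.
#' @param beta,K propagation parameters (defaults 0.5 and 2).
#' @param threshold hard-call threshold, typically from
#'   [calibrate_threshold()]; `NA` skips the hard calls.
#' @param cell_ids optional cell identifiers for the per-cell table.
#' @return An object of class `NoveltyResult`: list with `energy0`,
#'   `energyK`, `score` (= `-energyK`), `is_novel`, `threshold`, `beta`, `K`
#'   and a per-cell data frame `table`.
#' @export
detect_novel <- function(logits, graph, beta = 0.5, K = 2, threshold = NA,
                         cell_ids = NULL) {
  e0 <- energy_score(logits)
  B <- propagation_matrix(graph)
  eK <- propagate_energy(e0, B, beta = beta, K = K)
  score <- -eK
  is_novel <- if (is.na(threshold)) rep(NA, length(score)) else
    score < threshold
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_along(score))
  structure(list(
    energy0 = e0, energyK = eK, score = score, is_novel = is_novel,
    threshold = threshold, beta = beta, K = K,
    table = data.frame(cell_id = cell_ids, energy0 = e0, energyK = eK,
                       score = score, is_novel = is_novel)
  ), class = "NoveltyResult")
}

#' @export
print.NoveltyResult <- function(x, ...) {
  cat("NoveltyResult: ", length(x$score), " cells (beta = ", x$beta,
      ", K = ", x$K, ")", sep = "")
  if (!is.na(x$threshold)) {
    cat(sprintf(" | threshold %.4f -> %d novel call(s)", x$threshold,
                sum(x$is_novel)))
  }
  cat("\n")
  invisible(x)
}
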