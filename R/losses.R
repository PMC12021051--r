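#' Masked cross-entropy loss
#'
#' Mean over masked nodes of `-log softmax(logits)[true class]`, computed in
#' log-space via log-sum-exp, so arbitrarily large logits do not overflow.
#'
#' @param logits nodes x C matrix.
#' @param labels integer class per node in `1..C` (values outside the mask
#'   may be `NA`).
#' @param mask logical per-node vector selecting the labeled nodes; defaults
#'   to all nodes.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(logits, labels, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(logits))
  if (!any(mask)) stop("mask selects no nodes", call. = FALSE)
  l <- logits[mask, , drop = FALSE]
  y <- labels[mask]
  if (anyNA(y) || any(y < 1 | y > ncol(logits))) {
    stop("masked labels must lie in 1..", ncol(logits), call. = FALSE)
  }
  lse <- row_logsumexp(l)
  mean(lse - l[cbind(seq_len(nrow(l)), y)])
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

## Gradient of cross_entropy_loss w.r.t. logits (zero outside the mask).
cross_entropy_grad <- function(logits, labels, mask) {
  n <- nrow(logits)
  g <- matrix(0, n, ncol(logits))
  idx <- which(mask)
  l <- logits[idx, , drop = FALSE]
  p <- exp(l - row_logsumexp(l))
  p[cbind(seq_along(idx), labels[idx])] <-
    p[cbind(seq_along(idx), labels[idx])] - 1
  g[idx, ] <- p / length(idx)
  g
}

#' Negative log-likelihood of the zero-inflated negative binomial
#'
#' The ZINB mass mixes a point mass at zero (weight `pi`) with a negative
#' binomial of mean `mu` and dispersion `theta`:
#' zeros contribute `-log(pi + (1-pi) (theta/(theta+mu))^theta)` (evaluated
#' with a log-sum-exp), positives contribute
#' `-log(1-pi) - log NB(x; mu, theta)` with the log-gamma form of the NB
#' coefficient. Returns the mean over all entries.
#'
#' @param x non-negative count matrix (cells x genes) or vector.
#' @param pi,mu,theta ZINB parameters, same shape as `x` (scalars recycle).
#' @return Scalar mean negative log-likelihood.
#' @export
zinb_nll <- function(x, pi, mu, theta) {
  if (any(!is.finite(pi)) || any(!is.finite(mu)) || any(!is.finite(theta))) {
    stop("non-finite ZINB parameters", call. = FALSE)
  }
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  mean(zinb_nll_elementwise(x, pi, mu, theta))
}

## Per-entry NLL; scalar parameters recycle against x.
zinb_nll_elementwise <- function(x, pi, mu, theta) {
  x <- x + numeric(length(x))
  pi <- pi + 0 * x; mu <- mu + 0 * x; theta <- theta + 0 * x
  nll <- numeric(length(x))
  z <- which(x == 0)
  p <- which(x > 0)
  if (length(z)) {
    log_r <- log(theta[z]) - log(theta[z] + mu[z])
    # zero branch: logsumexp(log pi, log(1-pi) + theta*log(theta/(theta+mu)))
    a <- log(pi[z])
    b <- log1p(-pi[z]) + theta[z] * log_r
    m <- pmax(a, b)
    nll[z] <- -(m + log(exp(a - m) + exp(b - m)))
  }
  if (length(p)) {
    xp <- x[p]; pip <- pi[p]; mup <- mu[p]; thp <- theta[p]
    log_r <- log(thp) - log(thp + mup)
    nll[p] <- -(log1p(-pip) + lgamma(xp + thp) - lgamma(thp) -
                  lgamma(xp + 1) + thp * log_r +
                  xp * (log(mup) - log(thp + mup)))
  }
  dim(nll) <- dim(x)
  nll
}

## Mean ZINB NLL together with its gradients w.r.t. the head
## pre-activations (logit pi, log mu, log theta), exploiting
## dpi/dlogit = pi(1-pi), dmu/dlogmu = mu, dtheta/dlogtheta = theta.
## Shared subexpressions make this the training-loop workhorse; the zero and
## positive branches are evaluated on index subsets only.
zinb_loss_and_pregrad <- function(x, pi, mu, theta) {
  nll <- numeric(length(x))
  gpi <- numeric(length(x))
  gmu <- numeric(length(x))
  gth <- numeric(length(x))
  z <- which(x == 0)
  p <- which(x > 0)
  if (length(z)) {
    piz <- pi[z]; muz <- mu[z]; thz <- theta[z]
    log_r <- log(thz) - log(thz + muz)
    rt <- exp(thz * log_r)                  # NB(0) = (theta/(theta+mu))^theta
    a <- log(piz)
    b <- log1p(-piz) + thz * log_r
    m <- pmax(a, b)
    nll[z] <- -(m + log(exp(a - m) + exp(b - m)))
    p0 <- piz + (1 - piz) * rt
    gpi[z] <- -piz * (1 - piz) * (1 - rt) / p0
    gmu[z] <- muz * (1 - piz) * thz * rt / ((thz + muz) * p0)
    gth[z] <- -thz * (1 - piz) * rt * (log_r + muz / (thz + muz)) / p0
  }
  if (length(p)) {
    xp <- x[p]; pip <- pi[p]; mup <- mu[p]; thp <- theta[p]
    tm <- thp + mup
    log_r <- log(thp) - log(tm)
    nll[p] <- -(log1p(-pip) + lgamma(xp + thp) - lgamma(thp) -
                  lgamma(xp + 1) + thp * log_r + xp * (log(mup) - log(tm)))
    gpi[p] <- pip
    gmu[p] <- -(xp - mup * (xp + thp) / tm)
    gth[p] <- -thp * (digamma(xp + thp) - digamma(thp) + log_r + 1 -
                        thp / tm - xp / tm)
  }
  dm <- dim(x)
  dim(gpi) <- dm; dim(gmu) <- dm; dim(gth) <- dm
  list(nll = mean(nll), d_ppi = gpi, d_pmu = gmu, d_pth = gth)
}

## Gradient-only view (used by tests / ablation code paths).
zinb_nll_pregrad <- function(x, pi, mu, theta) {
  zinb_loss_and_pregrad(x, pi, mu, theta)[c("d_ppi", "d_pmu", "d_pth")]
}

#' Total training loss
#'
#' Weighted sum of the classification and reconstruction terms:
#' `l_cls + alpha * l_zinb`.
#'
#' @param l_cls,l_zinb scalar loss components.
#' @param alpha ZINB weight (default 1e-4).
#' @return Scalar total loss.
#' @export
total_loss <- function(l_cls, l_zinb, alpha = 1e-4) {
  stopifnot(is.finite(l_cls), is.finite(l_zinb), is.finite(alpha))
  l_cls + alpha * l_zinb
}
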