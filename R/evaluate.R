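#' Annotation metrics: accuracy, macro-F1, confusion matrix
#'
#' Accuracy is the fraction of masked cells whose prediction matches the
#' truth. Macro-F1 is the unweighted mean over true classes of per-class F1
#' (harmonic mean of precision and recall), with F1 = 0 for a class whose
#' precision + recall denominator is zero. The confusion matrix has true
#' classes as rows and predicted classes as columns.
#'
#' @param pred per-cell predicted labels.
#' @param truth per-cell true labels.
#' @param mask logical per-cell vector selecting the cells to score
#'   (default: all). Novel cells have no in-vocabulary truth label and should
#'   be excluded here; they are scored by the novelty metrics instead.
#' @param average `"macro"` (default), `"micro"` or `"weighted"` F1.
#' @return List with `accuracy`, `macro_f1`, `confusion`.
#' @export
annotation_metrics <- function(pred, truth, mask = NULL,
                               average = c("macro", "micro", "weighted")) {
  average <- match.arg(average)
  if (is.null(mask)) mask <- rep(TRUE, length(truth))
  if (!any(mask)) stop("mask selects no cells", call. = FALSE)
  pred <- as.character(pred)[mask]
  truth <- as.character(truth)[mask]
  levels <- sort(unique(c(truth, pred)))
  pf <- factor(pred, levels = levels)
  tf <- factor(truth, levels = levels)
  confusion <- table(truth = tf, predicted = pf)
  accuracy <- mean(pred == truth)
  true_classes <- sort(unique(truth))
  f1 <- vapply(true_classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  macro_f1 <- switch(average,
    macro = mean(f1),
    weighted = sum(f1 * as.numeric(table(tf)[true_classes])) / length(truth),
    micro = accuracy)  # single-label micro-F1 equals accuracy
  list(accuracy = accuracy, macro_f1 = macro_f1, confusion = confusion)
}

#' AUROC for novelty detection
#'
#' Probability that a randomly chosen known (in-distribution) cell scores
#' higher than a randomly chosen novel cell, with ties counted 1/2 — the
#' Mann-Whitney formulation of the area under the ROC curve for the
#' "low score means novel" convention.
#'
#' @param score per-cell novelty scores (low = novel).
#' @param is_novel_truth logical per-cell ground truth.
#' @return AUROC in `[0, 1]`.
#' @export
novelty_auroc <- function(score, is_novel_truth) {
  is_novel_truth <- as.logical(is_novel_truth)
  nk <- sum(!is_novel_truth)
  nn <- sum(is_novel_truth)
  if (nk == 0 || nn == 0) {
    stop("both known and novel cells are required", call. = FALSE)
  }
  r <- rank(score)  # midranks handle ties with 1/2 credit
  (sum(r[!is_novel_truth]) - nk * (nk + 1) / 2) / (nk * nn)
}

#' False-positive rate at a target true-positive rate
#'
#' The threshold is the largest value such that at least `tpr_target` of
#' known cells score at or above it (inclusive thresholding); the returned
#' FPR is the fraction of novel cells also scoring at or above that
#' threshold, i.e. mistaken for known.
#'
#' @inheritParams novelty_auroc
#' @param tpr_target known-cell retention rate (default 0.95).
#' @return FPR in `[0, 1]`.
#' @export
fpr_at_tpr <- function(score, is_novel_truth, tpr_target = 0.95) {
  is_novel_truth <- as.logical(is_novel_truth)
  sk <- score[!is_novel_truth]
  sn <- score[is_novel_truth]
  if (!length(sk) || !length(sn)) {
    stop("both known and novel cells are required", call. = FALSE)
  }
  m <- ceiling(tpr_target * length(sk))
  thr <- sort(sk, decreasing = TRUE)[m]
  mean(sn >= thr)
}

#' Full evaluation report
#'
#' Annotation metrics over test known cells plus novelty metrics over the
#' test pool (known vs novel).
#'
#' @param pred per-cell predicted labels.
#' @param truth per-cell true labels.
#' @param score per-cell novelty scores (low = novel).
#' @param splits a [make_splits()] assignment.
#' @return An object of class `EvalReport`: `accuracy`, `macro_f1`,
#'   `confusion`, `auroc`, `fpr95`, `n_test_known`, `n_novel`.
#' @export
eval_report <- function(pred, truth, score, splits) {
  known_test <- splits$test_mask & !splits$novel_mask
  ann <- annotation_metrics(pred, truth, known_test)
  have_novel <- any(splits$novel_mask)
  test_pool <- splits$test_mask
  auroc <- fpr95 <- NA_real_
  if (have_novel) {
    auroc <- novelty_auroc(score[test_pool], splits$novel_mask[test_pool])
    fpr95 <- fpr_at_tpr(score[test_pool], splits$novel_mask[test_pool])
  }
  structure(list(accuracy = ann$accuracy, macro_f1 = ann$macro_f1,
                 confusion = ann$confusion, auroc = auroc, fpr95 = fpr95,
                 n_test_known = sum(known_test),
                 n_novel = sum(splits$novel_mask)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(
    "EvalReport: accuracy %.4f | macro-F1 %.4f (%d test known cells)\n",
    x$accuracy, x$macro_f1, x$n_test_known))
  if (!is.na(x$auroc)) {
    cat(sprintf("            novelty AUROC %.4f | FPR@95TPR %.4f (%d novel cells)\n",
                x$auroc, x$fpr95, x$n_novel))
  }
  invisible(x)
}
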