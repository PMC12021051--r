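#' Train / validation / test split with a withheld novel class
#'
#' Cells are assigned to test (`test_frac`), validation (`val_frac`) and
#' training (remainder) by stratified-by-label random draws driven only by
#' `seed`. All cells of the withheld `novel_class` are then flagged in
#' `novel_mask`, removed from train and validation, and forced into the test
#' (inference) pool: a novel cell never contributes a training label or an
#' early-stopping signal.
#'
#' @param ds an [expression_dataset()] with labels.
#' @param test_frac,val_frac split fractions; `0 < test_frac + val_frac < 1`.
#' @param novel_class label to withhold; `"auto"` withholds the first class
#'   in sorted label order; `"random"` picks one class uniformly using
#'   `seed`; `NULL` withholds nothing (closed-set split).
#' @param seed integer driving all randomness.
#' @return An object of class `SplitAssignment`: logical `train_mask`,
#'   `val_mask`, `test_mask`, `novel_mask`, plus `novel_class` and `seed`.
#'   The three split masks partition the cells.
#' @export
make_splits <- function(ds, test_frac = 0.2, val_frac = 0.2,
                        novel_class = "auto", seed = 42) {
  if (is.null(ds$labels)) stop("dataset has no labels", call. = FALSE)
  if (!(test_frac + val_frac > 0 && test_frac + val_frac < 1)) {
    stop("need 0 < test_frac + val_frac < 1", call. = FALSE)
  }
  n <- n_cells(ds)
  labels <- ds$labels
  classes <- sort(unique(labels))
  if (!is.null(novel_class) && !identical(novel_class, "auto") &&
      !identical(novel_class, "random") && !novel_class %in% classes) {
    stop("novel_class '", novel_class, "' not present in labels",
         call. = FALSE)
  }
  small <- classes[table(labels)[classes] < 3]
  if (length(small)) {
    warning("class(es) ", paste(small, collapse = ", "),
            " have < 3 cells; stratified assignment is best-effort")
  }
  assign <- character(n)
  novel_class <- with_seed(seed, {
    if (identical(novel_class, "auto")) novel_class <- classes[1]
    if (identical(novel_class, "random")) novel_class <- sample(classes, 1)
    for (cl in classes) {
      idx <- which(labels == cl)
      m <- length(idx)
      idx <- sample(idx, m)
      n_test <- round(m * test_frac)
      n_val <- round(m * val_frac)
      if (n_test + n_val >= m) n_val <- max(0L, m - n_test - 1L)
      assign[idx] <- rep(c("test", "val", "train"),
                         c(n_test, n_val, m - n_test - n_val))
    }
    novel_class
  })
  novel_mask <- if (is.null(novel_class)) rep(FALSE, n) else
    labels == novel_class
  assign[novel_mask] <- "test"  # novel cells are evaluated, never trained on
  structure(list(
    train_mask = assign == "train",
    val_mask = assign == "val",
    test_mask = assign == "test",
    novel_mask = novel_mask,
    novel_class = if (is.null(novel_class)) NA_character_ else novel_class,
    seed = as.integer(seed)
  ), class = "SplitAssignment")
}

#' @export
print.SplitAssignment <- function(x, ...) {
  cat("SplitAssignment: train ", sum(x$train_mask), " / val ",
      sum(x$val_mask), " / test ", sum(x$test_mask),
      " (novel '", x$novel_class, "': ", sum(x$novel_mask), " cells)\n",
      sep = "")
  invisible(x)
}

## Evaluate `code` under a private RNG stream seeded with `seed`, restoring
## the caller's RNG state afterwards. All randomness in the package funnels
## through this helper so pipelines are reproducible from their seed alone.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
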