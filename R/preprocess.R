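#' Quality-control filtering of cells and genes
#'
#' Removes cells expressing (count > 0) fewer than `min_genes_per_cell` genes,
#' then genes expressed in fewer than `min_cells_per_gene` of the remaining
#' cells, in that order. The defaults are the usual real-data conventions;
#' for small simulated gene panels pass smaller thresholds. Idempotent for
#' fixed thresholds.
#'
#' @param ds an [expression_dataset()].
#' @param min_genes_per_cell,min_cells_per_gene non-negative integers.
#' @return The filtered dataset.
#' @export
filter_qc <- function(ds, min_genes_per_cell = 200, min_cells_per_gene = 3) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  genes_per_cell <- Matrix::rowSums(ds$counts > 0)
  keep_cells <- which(genes_per_cell >= min_genes_per_cell)
  if (!length(keep_cells)) {
    stop("QC removed every cell; relax min_genes_per_cell (currently ",
         min_genes_per_cell, ")", call. = FALSE)
  }
  sub <- ds$counts[keep_cells, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(sub > 0)
  keep_genes <- which(cells_per_gene >= min_cells_per_gene)
  if (!length(keep_genes)) {
    stop("QC removed every gene; relax min_cells_per_gene (currently ",
         min_cells_per_gene, ")", call. = FALSE)
  }
  subset_dataset(ds, cells = keep_cells, genes = keep_genes)
}

#' Library-size log-normalization
#'
#' Scales each cell to a common library size and applies `log1p`:
#' `normalized[i, j] = log(1 + counts[i, j] * target_sum / library_size(i))`.
#' Raw counts are retained unchanged alongside the normalized layer.
#'
#' @param ds an [expression_dataset()]; every cell must have a positive
#'   library size (run [filter_qc()] first).
#' @param target_sum common library size (default 10,000, the field
#'   convention).
#' @return The dataset with a `normalized` layer.
#' @export
normalize_log <- function(ds, target_sum = 1e4) {
  stopifnot(target_sum > 0)
  lib <- Matrix::rowSums(ds$counts)
  if (any(lib == 0)) {
    stop("cell(s) ", paste(utils::head(which(lib == 0), 5), collapse = ", "),
         " have zero library size; run filter_qc() first", call. = FALSE)
  }
  scaled <- as.matrix(ds$counts) * (target_sum / lib)
  ds$normalized <- log1p(scaled)
  ds
}

#' Highly variable gene selection (variance-stabilizing statistic)
#'
#' Ranks genes by the Seurat-v3-style variance-stabilized statistic computed
#' on raw counts: a loess of log10(variance) on log10(mean) (span 0.3) gives
#' each gene an expected standard deviation; counts are standardized with that
#' sd, clipped at `sqrt(n_cells)`, and genes are ranked by the variance of the
#' clipped standardized values. The top `min(n_top, n_genes)` genes are kept
#' and the matrices subset to them. Deterministic for fixed input.
#'
#' @param ds an [expression_dataset()] with raw counts.
#' @param n_top number of genes to keep (default 4000).
#' @return The dataset restricted to the selected genes, with `hvg_mask` set
#'   (all `TRUE` after subsetting; the pre-subset ranking is in
#'   `attr(, "hvg_rank")`).
#' @export
select_hvg <- function(ds, n_top = 4000) {
  if (n_top < 1) stop("n_top must be >= 1", call. = FALSE)
  g <- n_genes(ds)
  stat <- hvg_vst_statistic(ds$counts)
  # rank: larger standardized variance first; ties by gene order (stable)
  ord <- order(-stat, seq_len(g))
  keep <- sort(ord[seq_len(min(n_top, g))])
  out <- subset_dataset(ds, genes = keep)
  out$hvg_mask <- rep(TRUE, length(keep))
  attr(out, "hvg_rank") <- ord
  attr(out, "hvg_statistic") <- stat
  out
}

## Variance of clipped standardized counts per gene (the "vst" statistic).
hvg_vst_statistic <- function(counts, span = 0.3) {
  x <- as.matrix(counts)
  n <- nrow(x)
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  stat <- numeric(ncol(x))
  fit_idx <- which(v > 0 & mu > 0)
  if (length(fit_idx) < 2) return(stat)
  lf <- stats::loess(log10(v[fit_idx]) ~ log10(mu[fit_idx]), span = span,
                     degree = 2)
  sd_exp <- sqrt(10^stats::fitted(lf))
  clip <- sqrt(n)
  for (kk in seq_along(fit_idx)) {
    j <- fit_idx[kk]
    z <- (x[, j] - mu[j]) / sd_exp[kk]
    z <- pmin(z, clip)
    stat[j] <- sum(z^2) / (n - 1)
  }
  stat
}

#' Run the standard preprocessing chain
#'
#' [filter_qc()] then [normalize_log()] then [select_hvg()], with all
#' thresholds exposed. Convenience wrapper used by the pipeline presets.
#'
#' @param ds an [expression_dataset()].
#' @param min_genes_per_cell,min_cells_per_gene QC thresholds.
#' @param target_sum normalization target library size.
#' @param n_top number of highly variable genes.
#' @return The preprocessed dataset (normalized layer present, genes subset
#'   to HVGs).
#' @export
preprocess <- function(ds, min_genes_per_cell = 200, min_cells_per_gene = 3,
                       target_sum = 1e4, n_top = 4000) {
  ds <- filter_qc(ds, min_genes_per_cell, min_cells_per_gene)
  ds <- normalize_log(ds, target_sum)
  select_hvg(ds, n_top)
}
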