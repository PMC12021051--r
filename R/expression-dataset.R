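#' Construct an expression dataset
#'
#' Container for a cells x genes raw count matrix plus per-cell and per-gene
#' metadata. Cells are rows throughout the package. The raw counts are kept
#' alongside any derived layers: [normalize_log()] adds a `normalized` layer
#' (log1p of library-size-scaled counts) and [select_hvg()] records the highly
#' variable gene mask while subsetting both layers.
#'
#' @param counts cells x genes matrix of non-negative integer counts (base
#'   matrix or a [Matrix::sparseMatrix()]).
#' @param cell_ids character vector of length `nrow(counts)`; defaults to
#'   `cell_1..cell_n`.
#' @param gene_ids character vector of length `ncol(counts)`; defaults to
#'   `gene_1..gene_g`.
#' @param labels optional per-cell cell-type labels (character or factor);
#'   `NA` marks cells without a training label.
#' @param normalized optional normalized layer with the same dimensions.
#' @param hvg_mask optional per-gene logical mask of highly variable genes.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `counts`, `normalized`, `cell_ids`, `gene_ids`, `labels`, `hvg_mask`.
#' @export
#' @examples
#' ds <- expression_dataset(matrix(rpois(20, 2), nrow = 4))
#' dim(ds$counts)
expression_dataset <- function(counts, cell_ids = NULL, gene_ids = NULL,
                               labels = NULL, normalized = NULL,
                               hvg_mask = NULL) {
  counts <- as_count_matrix(counts)
  n <- nrow(counts)
  g <- ncol(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(g))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n) {
    stop("cell_ids length (", length(cell_ids), ") does not match n_cells (",
         n, ")", call. = FALSE)
  }
  if (length(gene_ids) != g) {
    stop("gene_ids length (", length(gene_ids), ") does not match n_genes (",
         g, ")", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) {
      stop("labels length (", length(labels), ") does not match n_cells (",
           n, ")", call. = FALSE)
    }
  }
  if (!is.null(normalized)) {
    normalized <- as.matrix(normalized)
    if (!all(dim(normalized) == c(n, g))) {
      stop("normalized layer dimensions do not match counts", call. = FALSE)
    }
  }
  if (!is.null(hvg_mask)) {
    stopifnot(is.logical(hvg_mask), length(hvg_mask) == g)
  }
  structure(
    list(counts = counts, normalized = normalized, cell_ids = cell_ids,
         gene_ids = gene_ids, labels = labels, hvg_mask = hvg_mask),
    class = "ExpressionDataset"
  )
}

## Validate and coerce a raw count matrix; errors name offending coordinates.
as_count_matrix <- function(counts) {
  if (inherits(counts, "sparseMatrix")) {
    counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
    vals <- counts@x
    if (length(vals)) {
      bad <- which(vals < 0 | vals != round(vals) | !is.finite(vals))
      if (length(bad)) {
        tr <- Matrix::summary(counts)
        stop("counts must be non-negative integers; offending entry at cell ",
             tr$i[bad[1]], ", gene ", tr$j[bad[1]], " (value ", vals[bad[1]],
             ")", call. = FALSE)
      }
    }
    return(counts)
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  bad <- which(counts < 0 | counts != round(counts) | !is.finite(counts))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(counts))
    stop("counts must be non-negative integers; offending entry at cell ",
         rc[1], ", gene ", rc[2], " (value ", counts[bad[1]], ")",
         call. = FALSE)
  }
  counts
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes\n", sep = "")
  cat("  layers: counts",
      if (!is.null(x$normalized)) ", normalized" else "",
      if (!is.null(x$hvg_mask)) paste0(" | hvg genes: ", sum(x$hvg_mask)) else "",
      "\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels, useNA = "ifany")
    cat("  labels: ", paste0(names(tab), " (", tab, ")", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Number of cells / genes in a dataset
#' @param ds an `ExpressionDataset`.
#' @return integer count.
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$counts)

## Subset cells and/or genes, keeping all layers aligned.
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(ds))
  if (is.null(genes)) genes <- seq_len(n_genes(ds))
  expression_dataset(
    counts = ds$counts[cells, genes, drop = FALSE],
    cell_ids = ds$cell_ids[cells],
    gene_ids = ds$gene_ids[genes],
    labels = if (!is.null(ds$labels)) ds$labels[cells],
    normalized = if (!is.null(ds$normalized))
      ds$normalized[cells, genes, drop = FALSE],
    hvg_mask = if (!is.null(ds$hvg_mask)) ds$hvg_mask[genes]
  )
}

## Dense matrix of raw counts (used by the ZINB loss and the simulator checks).
dense_counts <- function(ds) {
  as.matrix(ds$counts)
}
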