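#' Read a cells x genes count matrix
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx`}{Matrix Market file plus adjacent `genes.tsv` and
#'     `barcodes.tsv` (or explicit `genes_file` / `cells_file`). If the stored
#'     matrix is genes x cells (the common 10x convention) it is transposed so
#'     that cells are rows, using the identifier files to decide orientation.}
#'   \item{`csv` / `tsv`}{Dense table; header row = gene ids, first column =
#'     cell ids.}
#' }
#' HDF5 containers are not supported by this build (no R HDF5 bindings are
#' declared); requesting `format = "h5"` raises an informative error.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"mtx"`, `"csv"`, `"tsv"`, `"h5"`; `"auto"`
#'   (default) infers from the file extension.
#' @param genes_file,cells_file,labels_file optional companion files for the
#'   mtx format (one identifier per line; `labels_file` one label per cell).
#' @return An [expression_dataset()]. Cell and gene ordering of the input is
#'   preserved.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv", "h5"),
                        genes_file = NULL, cells_file = NULL,
                        labels_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     h5 = "h5", h5ad = "h5",
                     stop("cannot infer format from extension of '", path,
                          "'; pass format=", call. = FALSE))
  }
  if (format == "h5") {
    stop("HDF5 input is not supported by this installation; ",
         "export the matrix as MTX or CSV instead", call. = FALSE)
  }
  if (format == "mtx") {
    read_counts_mtx(path, genes_file, cells_file, labels_file)
  } else {
    read_counts_delim(path, sep = if (format == "csv") "," else "\t")
  }
}

read_counts_mtx <- function(path, genes_file, cells_file, labels_file) {
  m <- Matrix::readMM(path)
  dir <- dirname(path)
  stem <- sub("matrix\\.mtx$", "", basename(path))
  if (is.null(genes_file)) {
    genes_file <- first_existing(file.path(dir, c(
      paste0(stem, "genes.tsv"), "genes.tsv", "features.tsv",
      sub("\\.mtx$", "_genes.tsv", basename(path)))))
  }
  if (is.null(cells_file)) {
    cells_file <- first_existing(file.path(dir, c(
      paste0(stem, "barcodes.tsv"), "barcodes.tsv", "cells.tsv",
      sub("\\.mtx$", "_cells.tsv", basename(path)))))
  }
  gene_ids <- if (!is.null(genes_file)) read_id_column(genes_file)
  cell_ids <- if (!is.null(cells_file)) read_id_column(cells_file)
  # orient so cells are rows; when square, the cells-as-rows reading wins
  if (!is.null(gene_ids) && !is.null(cell_ids)) {
    if (nrow(m) == length(cell_ids) && ncol(m) == length(gene_ids)) {
      # already cells x genes
    } else if (nrow(m) == length(gene_ids) && ncol(m) == length(cell_ids)) {
      m <- Matrix::t(m)
    } else {
      stop("matrix is ", nrow(m), " x ", ncol(m),
           " but identifier files list ", length(cell_ids), " cells and ",
           length(gene_ids), " genes", call. = FALSE)
    }
  }
  labels <- NULL
  if (!is.null(labels_file)) {
    labels <- read_id_column(labels_file)
    if (length(labels) != nrow(m)) {
      stop("labels file lists ", length(labels), " entries for ", nrow(m),
           " cells", call. = FALSE)
    }
  }
  expression_dataset(m, cell_ids = cell_ids, gene_ids = gene_ids,
                     labels = labels)
}

read_counts_delim <- function(path, sep) {
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in '", path, "'",
                           call. = FALSE)
  expression_dataset(m, cell_ids = rownames(df), gene_ids = colnames(df))
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[1] else NULL
}

read_id_column <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  as.character(x[[1]])
}

#' Write a count matrix
#'
#' Inverse of [read_counts()] for the text formats: `mtx` writes the Matrix
#' Market file plus `<stem>_genes.tsv`, `<stem>_cells.tsv` and, when labels are
#' present, `<stem>_labels.tsv`; `csv`/`tsv` write a dense table with gene-id
#' header and cell-id first column. Raw counts round-trip bit-exactly.
#'
#' @param ds an [expression_dataset()].
#' @param path output file (for mtx, the `.mtx` file; companions are derived).
#' @param format `"mtx"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(ds, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- methods::as(methods::as(ds$counts, "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(m, path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(ds$gene_ids, paste0(stem, "_genes.tsv"))
    writeLines(ds$cell_ids, paste0(stem, "_cells.tsv"))
    if (!is.null(ds$labels)) writeLines(ds$labels, paste0(stem, "_labels.tsv"))
  } else {
    m <- as.matrix(ds$counts)
    dimnames(m) <- list(ds$cell_ids, ds$gene_ids)
    utils::write.table(cbind(cell_id = rownames(m), as.data.frame(m)),
                       path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a precomputed cell-graph edge list
#'
#' Two integer columns per line (TSV, no header), 1-based cell indices. The
#' graph is treated as undirected and simple: duplicate pairs and self-loops
#' are dropped.
#'
#' @param path edge-list file.
#' @param n_nodes number of cells in the graph.
#' @return A [cell_graph()].
#' @export
read_edge_list <- function(path, n_nodes) {
  e <- utils::read.table(path, sep = "\t", header = FALSE)
  cell_graph(n_nodes, as.matrix(e[, 1:2]), k = NA_integer_,
             metric = "precomputed")
}

#' Write a cell graph as an edge-list TSV (1-based, one undirected edge per
#' line with i < j).
#' @param graph a [cell_graph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
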