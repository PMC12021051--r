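#' Synthetic scRNA-seq configuration
#'
#' Generative model: each cell type owns a block of `markers_per_type` marker
#' genes whose negative-binomial mean is raised from `base_mu` to
#' `marker_mu`; counts are drawn NB(mean, `theta`) and then independently
#' zeroed with probability `pi0` (the dropout layer), i.e. entries follow the
#' same zero-inflated negative binomial the decoder models. `mixing` blends a
#' fraction of each cell's mean program with that of a random other type,
#' which pushes the induced KNN graph from homophily toward heterophily.
#'
#' With `two_hop_signal = TRUE` (requires `n_types = 4`) the generator
#' instead plants a graph in which type identity is not decidable from a
#' cell's own expression or its one-hop neighborhood: two "identity" types
#' share one marker program and two "relay" types share another; each
#' identity type wires only to its own relay type, and one relay community
#' carries extra internal edges, so the evidence separating the identity
#' types sits exactly two hops away. The planted edge list is returned in the
#' truth object.
#'
#' @param n_cells,n_genes,n_types problem dimensions (`n_types >= 2`,
#'   `markers_per_type * n_types <= n_genes`).
#' @param markers_per_type marker-block width per type.
#' @param base_mu,marker_mu background and marker NB means.
#' @param theta NB dispersion (smaller = more overdispersed).
#' @param pi0 gene-level zero-inflation probability in `[0, 1)`.
#' @param mixing fraction in `[0, 1]` of each cell's program taken from a
#'   random other type.
#' @param novel_type_index type withheld as the novel class (`NULL` for
#'   none; default 1, the first type).
#' @param two_hop_signal plant the two-hop-only label signal (see above).
#' @param relay_edges edges per cell used by the planted two-hop graph.
#' @param seed integer seed.
#' @return An object of class `SynthConfig`.
#' @export
synth_config <- function(n_cells = 800, n_genes = 300, n_types = 5,
                         markers_per_type = 20, base_mu = 1, marker_mu = 10,
                         theta = 2, pi0 = 0.15, mixing = 0,
                         novel_type_index = 1, two_hop_signal = FALSE,
                         relay_edges = 5, seed = 42) {
  if (length(novel_type_index) == 1 && is.na(novel_type_index)) {
    novel_type_index <- NULL  # NA is an accepted spelling of "none"
  }
  stopifnot(n_types >= 2, markers_per_type >= 1, base_mu > 0, marker_mu > 0,
            theta > 0, pi0 >= 0, pi0 < 1, mixing >= 0, mixing <= 1,
            n_cells >= n_types)
  if (markers_per_type * n_types > n_genes) {
    stop("markers_per_type * n_types (", markers_per_type * n_types,
         ") exceeds n_genes (", n_genes, ")", call. = FALSE)
  }
  if (two_hop_signal && n_types != 4) {
    stop("two_hop_signal requires n_types = 4 (two identity types + two ",
         "relay types)", call. = FALSE)
  }
  if (!is.null(novel_type_index)) {
    stopifnot(novel_type_index >= 1, novel_type_index <= n_types)
  }
  structure(as.list(environment()), class = "SynthConfig")
}

## Type x gene matrix of NB means (marker blocks on a background floor).
type_programs <- function(config) {
  prog <- matrix(config$base_mu, config$n_types, config$n_genes)
  for (t in seq_len(config$n_types)) {
    block <- ((t - 1) * config$markers_per_type + 1):
      (t * config$markers_per_type)
    prog[t, block] <- config$marker_mu
  }
  if (config$two_hop_signal) {
    # identity pair (1,2) shares program block A; relay pair (3,4) shares B
    m <- config$markers_per_type
    prog <- matrix(config$base_mu, 4, config$n_genes)
    prog[1, 1:m] <- config$marker_mu
    prog[2, 1:m] <- config$marker_mu
    prog[3, (m + 1):(2 * m)] <- config$marker_mu
    prog[4, (m + 1):(2 * m)] <- config$marker_mu
  }
  prog
}

#' Simulate a ZINB count matrix with type programs
#'
#' @param config a [synth_config()].
#' @return List with `dataset` (an [expression_dataset()] with labels
#'   `type_1..type_T`) and `truth`: `labels` (integer types), `mu`, `theta`,
#'   `pi` (per-cell-per-gene generative parameters), `novel_mask`, and, in
#'   two-hop mode, `planted_graph` (a [cell_graph()]).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  n <- config$n_cells
  g <- config$n_genes
  prog <- type_programs(config)
  out <- with_seed(config$seed, {
    types <- sample(rep_len(seq_len(config$n_types), n))
    mu_cells <- prog[types, , drop = FALSE]
    if (config$mixing > 0) {
      # additive blend: the partner's marker elevation is layered on top of
      # the cell's own program, scaled by `mixing`. Own markers stay at full
      # strength, so type identity remains recoverable at every mixing < 1
      # while within-type spread (random partner per cell) drives the KNN
      # graph toward heterophily. Blending models program sharing within the
      # known tissue continuum: the withheld novel type is a coherent
      # foreign population and takes part in neither direction of the blend.
      pool <- setdiff(seq_len(config$n_types), config$novel_type_index)
      blendable <- which(!(types %in% config$novel_type_index))
      other <- rep(NA_integer_, length(types))
      other[blendable] <- vapply(types[blendable], function(t) {
        cand <- setdiff(pool, t)
        if (!length(cand)) cand <- pool  # degenerate 2-type case
        cand[sample.int(length(cand), 1)]
      }, 1L)
      mu_cells[blendable, ] <- mu_cells[blendable, , drop = FALSE] +
        config$mixing * (prog[other[blendable], , drop = FALSE] -
                           config$base_mu)
    }
    counts <- matrix(stats::rnbinom(n * g, size = config$theta,
                                    mu = mu_cells), n, g)
    if (config$pi0 > 0) {
      drop <- matrix(stats::runif(n * g) < config$pi0, n, g)
      counts[drop] <- 0
    }
    planted <- if (config$two_hop_signal)
      plant_two_hop_graph(types, config$relay_edges)
    list(types = types, mu_cells = mu_cells, counts = counts,
         planted = planted)
  })
  labels <- paste0("type_", out$types)
  ds <- expression_dataset(out$counts, labels = labels)
  novel_mask <- if (is.null(config$novel_type_index)) rep(FALSE, n) else
    out$types == config$novel_type_index
  truth <- list(labels = out$types,
                mu = out$mu_cells,
                theta = matrix(config$theta, n, g),
                pi = matrix(config$pi0, n, g),
                novel_mask = novel_mask,
                planted_graph = out$planted)
  list(dataset = ds, truth = truth)
}

## Planted graph for the two-hop-signal mode. Each identity cell (types 1,2)
## is paired one-to-one with its own relay cell (types 3,4 respectively), so
## a one-hop view of an identity cell is always a single relay drawn from
## the shared relay program — carrying no class signal, not even a
## memorizable one (no relay serves two cells). Relay community 3 is
## additionally wired internally; community 4 is not. An identity cell's
## two-hop neighborhood is therefore either its relay's intra-community
## partners (type 1) or empty (type 2): the label evidence sits exactly two
## hops out. The relays themselves are separable at one hop (their
## neighborhoods do or do not contain relay-program mass).
plant_two_hop_graph <- function(types, relay_edges) {
  n <- length(types)
  i1 <- which(types == 1); i2 <- which(types == 2)
  i3 <- which(types == 3); i4 <- which(types == 4)
  n13 <- min(length(i1), length(i3))
  n24 <- min(length(i2), length(i4))
  from <- c(i1[seq_len(n13)], i2[seq_len(n24)])
  to <- c(sample(i3)[seq_len(n13)], sample(i4)[seq_len(n24)])
  for (i in i3) {
    pool <- setdiff(i3, i)
    nb <- pool[sample.int(length(pool), min(relay_edges, length(pool)))]
    from <- c(from, rep(i, length(nb))); to <- c(to, nb)
  }
  cell_graph(n, cbind(from, to), k = NA_integer_, metric = "planted")
}

#' Homophily of the KNN graph induced by a simulation
#'
#' Simulates counts, preprocesses with generator-scale defaults
#' (QC at `min_genes_per_cell = 10`, `min_cells_per_gene = 3`, target sum
#' 1e4, all genes kept as HVGs when the panel is small), builds the KNN
#' graph, and reports homophily — the calibration helper tying `mixing` to
#' the graph metrics.
#'
#' @param config a [synth_config()].
#' @param k KNN parameter (default 15).
#' @return A [homophily_report()].
#' @export
homophily_of_simulation <- function(config, k = 15) {
  sim <- simulate_counts(config)
  ds <- preprocess(sim$dataset, min_genes_per_cell = 10,
                   min_cells_per_gene = 3, n_top = 4000)
  graph <- build_knn_graph(ds, k = k)
  homophily_report(graph, ds$labels)
}
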