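# Small deterministic fixtures shared across test files.

toy_counts <- function() {
  # 3 cells x 2 genes: ((0,1),(2,0),(5,3))
  matrix(c(0, 2, 5, 1, 0, 3), nrow = 3,
         dimnames = list(paste0("c", 1:3), paste0("g", 1:2)))
}

toy_dataset <- function() expression_dataset(toy_counts())

# path graph a-b-c over 3 nodes
path3 <- function() cell_graph(3, rbind(c(1, 2), c(2, 3)))

triangle <- function() cell_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))

# Quick small simulation + preprocessing used by model-level tests.
quick_sim <- function(n_cells = 120, n_genes = 100, n_types = 4, seed = 1,
                      ...) {
  cfg <- synth_config(n_cells = n_cells, n_genes = n_genes,
                      n_types = n_types,
                      markers_per_type = min(10, n_genes %/% n_types),
                      seed = seed, ...)
  sim <- simulate_counts(cfg)
  ds <- preprocess(sim$dataset, min_genes_per_cell = 5,
                   min_cells_per_gene = 2, n_top = n_genes)
  list(ds = ds, truth = sim$truth, cfg = cfg)
}

# Random Erdos-Renyi style graph with at least one edge.
random_graph <- function(n, p = 0.2) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  cell_graph(n, pairs[keep, , drop = FALSE])
}

# Independent brute-force homophily oracles (double loop over the
# definitions).
oracle_node_homophily <- function(graph, labels) {
  A <- as.matrix(adjacency_matrix(graph))
  fr <- c()
  for (i in seq_len(graph$n_nodes)) {
    nb <- which(A[i, ] > 0)
    if (length(nb)) fr <- c(fr, mean(labels[nb] == labels[i]))
  }
  mean(fr)
}

oracle_edge_homophily <- function(graph, labels) {
  e <- graph$edges
  sum(labels[e[, 1]] == labels[e[, 2]]) / nrow(e)
}

# Direct (non-log-space) ZINB pmf via the base-R negative binomial.
oracle_zinb_nll <- function(x, pi, mu, theta) {
  pmf <- pi * (x == 0) + (1 - pi) * dnbinom(x, size = theta, mu = mu)
  -mean(log(pmf))
}

# Exhaustive-pair AUROC oracle with half credit for ties.
oracle_auroc <- function(score, is_novel) {
  sk <- score[!is_novel]
  sn <- score[is_novel]
  tot <- 0
  for (a in sk) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sk) * length(sn))
}

# Brute-force threshold sweep for FPR at a TPR target.
oracle_fpr_at_tpr <- function(score, is_novel, tpr_target = 0.95) {
  sk <- score[!is_novel]
  sn <- score[is_novel]
  cand <- sort(unique(score), decreasing = TRUE)
  thr <- NA
  for (t in cand) {
    if (mean(sk >= t) >= tpr_target) { thr <- t; break }
  }
  mean(sn >= thr)
}
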