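#' Pipeline configuration
#'
#' Layered configuration for the end-to-end run. Defaults equal the reference
#' protocol wherever one exists (20%/20% test/validation split, KNN `k = 15`,
#' widths 32, 200 epochs of Adam at learning rate 1e-2 with weight decay
#' 5e-3, ZINB weight 1e-4, propagation `beta = 0.5`, seeds
#' 42/66/88/2023/2024). Unknown keys are rejected.
#'
#' @param preset optional simulation preset: `"homophilous"` (mixing 0),
#'   `"heterophilous"` (mixing 0.8), `"two-hop"` (planted two-hop label
#'   signal), `"novelty-demo"` (mixing 0.5, one withheld type).
#' @param ... overrides as nested lists, e.g.
#'   `training = list(epochs = 50)`; section and key names must match the
#'   defaults.
#' @return Nested configuration list of class `PipelineConfig`.
#' @export
pipeline_config <- function(preset = NULL, ...) {
  cfg <- list(
    simulation = list(n_cells = 800, n_genes = 300, n_types = 5,
                      markers_per_type = 20, base_mu = 1, marker_mu = 10,
                      theta = 2, pi0 = 0.15, mixing = 0, novel_type_index = 1,
                      two_hop_signal = FALSE, relay_edges = 5),
    data = list(counts = NULL, labels = NULL, edge_list = NULL),
    preprocessing = list(min_genes_per_cell = 10, min_cells_per_gene = 3,
                         target_sum = 1e4, n_top = 4000),
    graph = list(k = 15, metric = "euclidean", use_planted = FALSE),
    split = list(test_frac = 0.2, val_frac = 0.2, novel_class = "auto"),
    encoder = list(extract_dim = 32, hidden_dim = 32, n_graph_layers = 1,
                   activation = "relu", bias = TRUE, mean_aggregate = TRUE,
                   two_hop = TRUE),
    training = list(epochs = 200, learning_rate = 1e-2, weight_decay = 5e-3,
                    alpha_zinb = 1e-4, selection = "best"),
    novelty = list(beta = 0.5, K = 2, tpr_target = 0.95),
    seeds = c(42, 66, 88, 2023, 2024)
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("homophilous", "heterophilous", "two-hop",
                                  "novelty-demo"))
    cfg$simulation <- utils::modifyList(cfg$simulation, switch(preset,
      homophilous = list(mixing = 0),
      heterophilous = list(mixing = 0.8),
      `two-hop` = list(n_types = 4, two_hop_signal = TRUE,
                       novel_type_index = NA),
      `novelty-demo` = list(mixing = 0.5)))
    if (preset == "two-hop") {
      cfg$graph$use_planted <- TRUE
      cfg$split$novel_class <- NULL
    }
  }
  overrides <- list(...)
  check_config_keys(overrides, cfg)
  cfg <- modify_config(cfg, overrides)
  structure(cfg, class = "PipelineConfig")
}

check_config_keys <- function(overrides, template) {
  bad <- setdiff(names(overrides), names(template))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (is.list(template[[nm]]) && is.list(overrides[[nm]])) {
      bad <- setdiff(names(overrides[[nm]]), names(template[[nm]]))
      if (length(bad)) {
        stop("unknown configuration key(s) in section '", nm, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

## modifyList that allows setting entries to NULL explicitly.
modify_config <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][k] <- overrides[[nm]][k]
    } else {
      cfg[nm] <- overrides[nm]
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file; keys must match [pipeline_config()] sections.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- raw$preset
  raw$preset <- NULL
  do.call(pipeline_config, c(list(preset = preset), raw))
}

#' Run one seed of the full experiment
#'
#' simulate (or load) -> preprocess -> graph -> splits -> train ->
#' novelty detection -> evaluation, with every random draw tied to `seed`.
#'
#' @param config a [pipeline_config()].
#' @param seed integer seed for this replicate.
#' @return List with `metrics` (named list of scalar metrics), `fit`,
#'   `novelty`, `pred`, `splits`, `ds` (preprocessed dataset), `graph`,
#'   `homophily`.
#' @export
run_seed_experiment <- function(config, seed) {
  sim <- NULL
  if (is.null(config$data$counts)) {
    scfg <- do.call(synth_config, c(config$simulation, list(seed = seed)))
    sim <- simulate_counts(scfg)
    ds <- sim$dataset
  } else {
    ds <- read_counts(config$data$counts,
                      labels_file = config$data$labels)
  }
  pp <- config$preprocessing
  n_before <- n_cells(ds)
  ds <- preprocess(ds, min_genes_per_cell = pp$min_genes_per_cell,
                   min_cells_per_gene = pp$min_cells_per_gene,
                   target_sum = pp$target_sum, n_top = pp$n_top)
  graph <- if (config$graph$use_planted && !is.null(sim)) {
    if (n_cells(ds) != n_before) {
      stop("QC removed cells, so the planted graph no longer aligns; ",
           "lower min_genes_per_cell", call. = FALSE)
    }
    sim$truth$planted_graph
  } else if (!is.null(config$data$edge_list)) {
    read_edge_list(config$data$edge_list, n_cells(ds))
  } else {
    build_knn_graph(ds, k = config$graph$k, metric = config$graph$metric)
  }
  hom <- homophily_report(graph, ds$labels)
  splits <- make_splits(ds, test_frac = config$split$test_frac,
                        val_frac = config$split$val_frac,
                        novel_class = config$split$novel_class, seed = seed)
  enc <- do.call(encoder_config, c(
    list(in_dim = n_genes(ds),
         n_classes = length(unique(ds$labels[!splits$novel_mask]))),
    config$encoder, list(seed = seed)))
  tcfg <- do.call(train_config, c(config$training, list(seed = seed)))
  fit <- train_heteronet(ds, graph, splits, enc = enc, cfg = tcfg)
  pred <- predict_heteronet(fit, ds, graph)
  nov <- detect_novel(pred$logits, graph, beta = config$novelty$beta,
                      K = config$novelty$K, cell_ids = ds$cell_ids)
  val_known <- splits$val_mask & !splits$novel_mask
  thr <- if (sum(val_known) >= 20)
    calibrate_threshold(nov$score[val_known], config$novelty$tpr_target)
  else NA_real_
  if (!is.na(thr)) {
    nov$threshold <- thr
    nov$is_novel <- nov$score < thr
    nov$table$is_novel <- nov$is_novel
  }
  report <- eval_report(pred$pred, ds$labels, nov$score, splits)
  metrics <- list(seed = seed,
                  accuracy = report$accuracy,
                  macro_f1 = report$macro_f1,
                  auroc = report$auroc,
                  fpr95 = report$fpr95,
                  node_homophily = hom$node_homophily,
                  edge_homophily = hom$edge_homophily,
                  n_test_known = report$n_test_known,
                  n_novel = report$n_novel,
                  best_epoch = fit$best_epoch)
  list(metrics = metrics, fit = fit, novelty = nov, pred = pred,
       splits = splits, ds = ds, graph = graph, homophily = hom,
       report = report)
}

#' Run the multi-seed pipeline and persist artifacts
#'
#' Executes [run_seed_experiment()] for every seed in the configuration and
#' writes, under `out_dir`: per-seed metric JSONs, a `summary.json` with
#' mean and standard deviation of each metric, per-seed embeddings (TSV),
#' per-seed novelty tables (TSV), model checkpoints, and a provenance record
#' (`provenance.json`: configuration, seeds, package version). Metric files
#' contain no timestamps, so two runs with the same configuration are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param save_checkpoints write per-seed `ModelState` files (default TRUE).
#' @return Invisibly, the list of per-seed metric lists plus the summary.
#' @export
run_pipeline <- function(config, out_dir, save_checkpoints = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_metrics <- list()
  for (seed in config$seeds) {
    res <- run_seed_experiment(config, seed)
    tag <- paste0("seed_", seed)
    write_json_file(res$metrics, file.path(out_dir,
                                           paste0("metrics_", tag, ".json")))
    emb <- data.frame(cell_id = res$ds$cell_ids, res$pred$Z,
                      check.names = FALSE)
    utils::write.table(emb, file.path(out_dir,
                                      paste0("embedding_", tag, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$novelty$table,
                       file.path(out_dir, paste0("novelty_", tag, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (save_checkpoints) {
      save_checkpoint(res$fit$state,
                      file.path(out_dir, paste0("checkpoint_", tag, ".rds")))
    }
    all_metrics[[tag]] <- res$metrics
  }
  num <- c("accuracy", "macro_f1", "auroc", "fpr95", "node_homophily",
           "edge_homophily")
  summary <- lapply(num, function(m) {
    v <- vapply(all_metrics, function(x)
      if (is.null(x[[m]]) || is.na(x[[m]])) NA_real_ else x[[m]], 0)
    list(mean = mean(v, na.rm = TRUE),
         sd = if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  })
  names(summary) <- num
  write_json_file(summary, file.path(out_dir, "summary.json"))
  write_json_file(list(config = unclass(config),
                       seeds = config$seeds,
                       package_version =
                         as.character(utils::packageVersion("heterocell"))),
                  file.path(out_dir, "provenance.json"))
  invisible(list(per_seed = all_metrics, summary = summary))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
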