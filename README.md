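# heterocell

Heterophily-aware cell-type annotation and novel cell detection for
single-cell RNA-seq.

## What it does, and for whom

Annotating scRNA-seq cells by propagating labels over a KNN cell graph
works well when neighbors share a type (homophily) and degrades badly when
they do not. Many real datasets — intermixed tumor microenvironments,
developmental continua, infected tissues — are substantially
*heterophilous*. `heterocell` is for analysts who want graph-based
annotation that holds up in that regime, and who additionally need to know
when a cell belongs to **no** training class (a novel / previously
uncharacterized type) rather than being force-assigned a known label.

Two ideas do the work:

1. **Heterophily-aware encoder.** Each graph layer keeps three separate
   weight matrices for the self term, the one-hop neighbor sum and the
   exactly-two-hop neighbor sum,

   h_i^(l+1) = σ( W0 h_i^(l) + Σ_{j∈N_i} W1 h_j^(l) + Σ_{k∈N(N_i)} W2 h_k^(l) ),

   and the final embedding Z concatenates every layer's activations, so
   graph-free features survive next to wide-receptive-field ones. A linear
   head on Z gives class logits. Training minimizes
   L = L_cls + α·L_ZINB, where L_ZINB is the negative log-likelihood of
   the raw counts under a zero-inflated negative binomial decoded from Z
   (dropout Π by a logistic link, mean M and dispersion Θ by exponential
   links).

2. **Energy-based novelty with graph propagation.** Per-cell energy
   E = −log Σ_c exp(logit_c) is high for cells unlike every training
   class. Energies are smoothed over the within-two-hop neighborhood,
   E^k = β E^(k−1) + (1−β) B E^(k−1) with B row-stochastic, and the score
   −E^K is thresholded (calibrated at 95% known-cell retention on
   validation cells) to call novel cells.

The package also ships the surrounding tooling: MTX/CSV/TSV readers and
writers, QC filtering, library-size log-normalization, variance-stabilized
HVG selection, deterministic KNN graph construction, node/edge homophily
metrics, annotation and open-set metrics (accuracy, macro-F1, AUROC,
FPR@95%TPR), a ZINB count simulator with a tunable heterophily dial and a
designated novel type, and a multi-seed pipeline with a thin CLI
(`inst/cli/heterocell`).

## Worked example

Simulate a homophilous five-type benchmark, withhold the first type as
novel, train with the default protocol (200 epochs, Adam, lr 1e-2, weight
decay 5e-3, ZINB weight 1e-4), and evaluate:

```r
library(heterocell)

cfg <- pipeline_config(preset = "homophilous", seeds = c(42))
res <- run_seed_experiment(cfg, seed = 42)

res$homophily
#> HomophilyReport: node 0.9395 | edge 0.9466 | 0 isolated node(s)
res$fit
#> HeteronetFit: 4 known classes, 200 epochs trained | final l_total 0.0010 | best val acc 1.000 (epoch 52)
res$report
#> EvalReport: accuracy 1.0000 | macro-F1 1.0000 (128 test known cells)
#>             novelty AUROC 1.0000 | FPR@95TPR 0.0000 (160 novel cells)
res$novelty
#> NoveltyResult: 800 cells (beta = 0.5, K = 2) | threshold 14.2465 -> 187 novel call(s)
```

Reading the output: the KNN graph of the mixing-free simulation is strongly
homophilous (edge homophily 0.95); the four known types are annotated
perfectly on the 128 held-out known cells; the 160 cells of the withheld
type rank strictly below every known test cell in novelty score (AUROC 1.0,
no false positives at 95% TPR), and the calibrated threshold flags 187
cells — the 160 truly novel ones plus 27 borderline known cells, the price
of retaining 95% of known cells by construction.

The same flow composes from parts: `read_counts()` → `preprocess()` →
`build_knn_graph()` → `make_splits()` → `train_heteronet()` →
`predict_heteronet()` → `detect_novel()` → `eval_report()`. The methods
vignette (`vignettes/heterocell-methods.Rmd`) documents the model, every
default, and the generator's design.

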