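# oncogrn

Reconstruction and interrogation of **cancer type-specific gene regulatory
networks (GRNs)** from expression data, for computational biologists studying
how transcriptional programs distinguish tumor types from each other and from
normal tissue.

Given a multi-class expression corpus (gene-by-sample intensities plus a
sample metatable) and a gold-standard list of transcription factor (TF) →
target pairs, the package:

- restricts association scoring to the gold standard, background-corrects it
  CLR-style, and retains a weighted TF→target network:
  `z_ij = sqrt((max(0,z_i)² + max(0,z_j)²)/2)`, where `z_i` standardizes
  `|ρ_ij|` within gene *i*'s association row; edges kept at `z_ij ≥ 2`;
- detects subnetworks with InfoMap and assigns them to cancer types by
  hypergeometric enrichment in class-specific template genes;
- trains one balanced random forest per type (one-vs-rest, 1000 trees,
  compiled from scratch in C++) and scores samples by vote fraction —
  evaluated with precision–sensitivity curves and their area (AUPR);
- quantifies **GRN status**: per GRN gene, `s_g = (z_cap − |z_g|)/z_cap` with
  `z_g` the capped z-score against the class training distribution; the
  importance-weighted mean is standardized so training samples of the class
  average 100%;
- ranks TFs by **network influence score**
  `NIS(t) = w_t·z̄_t + Σ_g w_g·z̄_g·sign(t,g)` over the TF's GRN targets
  (most negative = most under-established subnetwork in the query);
- relates single-gene expression to survival: Kaplan–Meier estimation,
  log-rank test, Breslow Cox regression, and a best-cutoff scan over all
  observed values strictly between the expression quartiles, gated at
  BH FDR < 10% with the smallest-p cutoff selected.

A first-class synthetic-data module generates multi-class corpora with
planted TF hubs, matched/attenuated/silenced query samples, and survival
cohorts with a planted cutoff effect, so every stage is testable offline.

## Worked example

```r
library(oncogrn)

cfg    <- sim_config(n_classes = 6, n_tfs_per_class = 2, targets_per_tf = 4,
                     n_background_genes = 200, samples_per_class = 10,
                     hub_effect = 4, noise_sd = 0.5, decoy_pairs = 20, seed = 42)
gs     <- generate_gold_standard(cfg)
corpus <- simulate_corpus(cfg, gs$truth)
expr   <- normalize_total(corpus$expr)                 # columns sum to 1e5
labels <- setNames(corpus$sample_table$description,
                   corpus$sample_table$sample_id)

split <- split_half(corpus$sample_table, seed = 1)     # stratified 50/50
tmpl  <- class_template_scores(expr[, split$train], labels[split$train])
net   <- reconstruct_network(expr[, split$train], gs$gold_standard)
part  <- detect_communities(net, seed = 1)
grns  <- assign_subnetworks(part, tmpl, net, top_k = 30)
model <- train_classifiers(expr[, split$train], labels[split$train],
                           grns, tmpl, ntree = 500, top_k = 30, seed = 1)
ev    <- evaluate_all(model, expr[, split$validation],
                      labels[split$validation], n_boot = 100, seed = 1)
ev$mean_aupr
#> [1] 1
```

Every validation sample is classified perfectly (the planted 4-fold hubs are
well separated at this noise level); each class's AUPR is 1 with a degenerate
bootstrap CI. GRN status of matched-type queries scatters around ~95% of the
training level:

```r
stats <- fit_training_stats(expr[, split$train], labels[split$train],
                            model$class_grns)
q <- normalize_total(simulate_query(cfg, gs$truth, "class03",
                                    attenuation = 1, n = 5, seed = 2))
round(grn_status(q, "class03", stats), 1)
#> query_class03_01 query_class03_02 query_class03_03 query_class03_04 query_class03_05
#>             92.3            107.4             88.7             92.7             84.8
```

Silencing one planted TF hub in the query drives that TF to NIS rank 1 with a
strongly negative score (its subnetwork is under-established), while the
intact hub sits near 0:

```r
tf <- gs$truth$class_tfs[["class03"]][1]
qs <- normalize_total(simulate_silenced_query(cfg, gs$truth, "class03", tf,
                                              n = 5, seed = 3))
network_influence(qs, "class03", model$class_grns[["class03"]], stats)
#>     class        tf         nis rank
#> 1 class03 TF_c03_01 -0.70816721    1
#> 2 class03 TF_c03_02 -0.01649312    2
```

The survival scan recovers a planted cutoff (true value 100) and its hazard
effect (true HR = exp(1.5) ≈ 4.5, attenuated by censoring and the step
split):

```r
d   <- simulate_survival(survival_sim_config(n_patients = 300, beta = 1.5,
                                             censor_rate = 0.2,
                                             true_cutoff = 100, seed = 4))
res <- scan_cutoffs(d, fdr = 0.10)
res$best
#> best cutoff 101.30, p = 9.58e-24, q = 1.44e-21, HR = 3.84
```

`run_pipeline(default_config(...), out_dir)` chains all stages and writes the
artifact set (classification score matrix, PR curves and AUC summary, GraphML
networks, GRN structural metrics, GRN-status and NIS tables), each stamped
with a hash of the resolved configuration.

## Package layout

- `R/synthetic-data.R` — corpus/query/survival generators and file formats
- `R/preprocessing.R` — probe collapsing, total normalization, array QC
- `R/grn.R` — template scores, CLR network, communities, class assignment,
  metrics, GraphML export
- `R/classifier.R`, `src/rf.cpp` — balanced one-vs-rest random forests,
  PR curves, bootstrap evaluation
- `R/grn-status.R` — training statistics (moderated variances) and GRN status
- `R/network-influence.R` — NIS tables
- `R/survival.R` — KM / log-rank / Cox / quartile-bounded cutoff scan
- `R/pipeline.R` — metatable I/O, run configuration, end-to-end runner
- `vignettes/methods.Rmd` — the model, its assumptions, parameter choices,
  and known limitations
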