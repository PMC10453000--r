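# Shared fixtures. Everything is generated in code at test time; the "small
# world" keeps per-class prevalence realistic enough (6 classes) for the
# correlation-based network stage while staying fast.

small_world_env <- new.env()

small_world <- function() {
  if (!is.null(small_world_env$w)) return(small_world_env$w)
  cfg <- sim_config(n_classes = 6, n_tfs_per_class = 2, targets_per_tf = 4,
                    n_background_genes = 200, samples_per_class = 10,
                    hub_effect = 4, noise_sd = 0.5, decoy_pairs = 20,
                    seed = 42)
  gs <- generate_gold_standard(cfg)
  corpus <- simulate_corpus(cfg, gs$truth)
  expr <- normalize_total(corpus$expr)
  labels <- setNames(corpus$sample_table$description,
                     corpus$sample_table$sample_id)
  small_world_env$w <- list(cfg = cfg, truth = gs$truth,
                            gold = gs$gold_standard,
                            sample_table = corpus$sample_table,
                            raw = corpus$expr, expr = expr, labels = labels)
  small_world_env$w
}

# small trained world: network, GRNs, classifier, stats (memoized)
trained_world <- function() {
  if (!is.null(small_world_env$tw)) return(small_world_env$tw)
  w <- small_world()
  net <- reconstruct_network(w$expr, w$gold, z_threshold = 2)
  part <- detect_communities(net, seed = 1)
  tmpl <- class_template_scores(w$expr, w$labels)
  grns <- assign_subnetworks(part, tmpl, net, top_k = 30)
  model <- train_classifiers(w$expr, w$labels, grns, tmpl,
                             ntree = 300, top_k = 30, seed = 5)
  stats <- fit_training_stats(w$expr, w$labels, model$class_grns)
  small_world_env$tw <- list(w = w, net = net, partition = part,
                             templates = tmpl, grns = model$class_grns,
                             model = model, stats = stats)
  small_world_env$tw
}

planted_genes_of <- function(truth, class) {
  tfs <- truth$class_tfs[[class]]
  c(tfs, unlist(truth$tf_targets[tfs], use.names = FALSE))
}

# independent brute-force PR curve: confusion counts per cutoff via table()
oracle_pr <- function(scores, truth) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(cuts, function(ct) {
    call <- factor(scores >= ct, levels = c(FALSE, TRUE))
    tr <- factor(truth == 1, levels = c(FALSE, TRUE))
    tab <- table(call, tr)
    tp <- tab["TRUE", "TRUE"]; fp <- tab["TRUE", "FALSE"]
    fn <- tab["FALSE", "TRUE"]
    c(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
      sensitivity = tp / (tp + fn))
  })
  m <- do.call(rbind, rows)
  auc <- sum(diff(c(0, m[, "sensitivity"])) * m[, "precision"])
  list(curve = m, auc = auc)
}

# adjusted Rand index between two labelings (contingency-table formula)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
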