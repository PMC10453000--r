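#' Read and validate a sample metatable
#'
#' The metatable holds one row per expression sample: a distinct sample
#' identifier, the raw file name, and an annotation naming the experimental
#' group (training class or query group).
#'
#' @param path CSV with columns sample_id, file_name, description
#' @return validated data.frame
#' @export
read_sample_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "file_name", "description")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop(sprintf("sample table missing column(s): %s",
                 paste(missing, collapse = ", ")))
  bad <- which(is.na(df$sample_id) | df$sample_id == "" |
                 is.na(df$description) | df$description == "")
  if (length(bad) > 0)
    stop(sprintf("malformed sample table row %d (empty id or description)",
                 bad[1]))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0)
    stop(sprintf("duplicated sample_id: %s", dup[1]))
  df[, need]
}

#' @rdname read_sample_table
#' @param x a sample table
#' @param path output CSV path
#' @export
write_sample_table <- function(x, path) {
  write.csv(x[, c("sample_id", "file_name", "description")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' One document holding every stage's parameters. A single global `seed` fans
#' out deterministically to per-stage seeds. Readable from YAML with
#' [read_run_config()]; unknown keys are rejected.
#'
#' @param ... overrides of the defaults
#' @return named list of class `run_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic corpus (used when no input paths are given)
    n_classes = 17L, n_tfs_per_class = 5L, targets_per_tf = 10L,
    n_background_genes = 1000L, samples_per_class = 20L,
    hub_effect = 4, noise_sd = 0.5, decoy_pairs = 100L, baseline = 100,
    # optional real inputs
    expression_path = NULL, sample_table_path = NULL, gold_standard_path = NULL,
    query_expression_path = NULL,
    # preprocessing
    normalize_scale = 1e5, qc_k_mad = 5,
    # network
    association_method = "pearson", z_threshold = 2,
    community_method = "infomap", top_k = 100L, alpha = 0.05,
    # classifier
    ntree = 1000L, n_boot = 200L,
    # status
    z_cap = 3, sigma_floor_frac = 1e-3,
    # query simulation for the reporting stage
    n_query_per_class = 10L, attenuation = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname default_config
#' @param path YAML file of overrides
#' @export
read_run_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full pipeline and write its artifact directory
#'
#' Stages: corpus (simulated or loaded) -> QC + total normalization ->
#' stratified half split -> template scores -> gold-standard-restricted
#' network -> community detection -> subnetwork-to-class assignment ->
#' one-vs-rest forests -> validation scoring (classification heatmap data,
#' precision-sensitivity curves, per-class and mean AUC) -> GRN status of
#' validation and matched query samples -> network influence tables ->
#' GraphML exports and structural metrics. Every output file embeds the
#' resolved configuration hash; any stage failure aborts with the stage name.
#'
#' @param config a `run_config` from [default_config()]
#' @param out_dir artifact directory (created if absent)
#' @return invisibly, a list with the in-memory results and `hash`
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run_")) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  stage <- "init"
  result <- tryCatch({
    logf("config hash %s, seed %d", hash, config$seed)

    stage <- "corpus"
    simulated <- is.null(config$expression_path)
    if (simulated) {
      sc <- sim_config(n_classes = config$n_classes,
                       n_tfs_per_class = config$n_tfs_per_class,
                       targets_per_tf = config$targets_per_tf,
                       n_background_genes = config$n_background_genes,
                       samples_per_class = config$samples_per_class,
                       hub_effect = config$hub_effect,
                       noise_sd = config$noise_sd,
                       decoy_pairs = config$decoy_pairs,
                       baseline = config$baseline,
                       seed = derive_seed(config$seed, "sim"))
      gs <- generate_gold_standard(sc)
      corpus <- simulate_corpus(sc, gs$truth)
      gold <- gs$gold_standard
      sample_table <- corpus$sample_table
      expr_raw <- corpus$expr
    } else {
      expr_raw <- read_expression(config$expression_path)
      sample_table <- read_sample_table(config$sample_table_path)
      gold <- read_gold_standard(config$gold_standard_path)
    }
    logf("corpus: %d genes x %d samples, %d gold pairs",
         nrow(expr_raw), ncol(expr_raw), nrow(gold))

    stage <- "preprocess"
    qc <- qc_filter(expr_raw, k_mad = config$qc_k_mad)
    expr_raw <- expr_raw[, qc$kept, drop = FALSE]
    sample_table <- sample_table[sample_table$sample_id %in% qc$kept, ]
    expr <- normalize_total(expr_raw, scale = config$normalize_scale)
    write_tsv_stamped(qc$report, file.path(out_dir, "qc_report.tsv"), hash)

    stage <- "split"
    split <- split_half(sample_table, seed = config$seed)
    labels <- setNames(sample_table$description, sample_table$sample_id)
    expr_train <- expr[, split$train, drop = FALSE]
    expr_valid <- expr[, split$validation, drop = FALSE]

    stage <- "templates"
    templates <- class_template_scores(expr_train, labels[split$train])

    stage <- "network"
    net <- reconstruct_network(expr_train, gold,
                               z_threshold = config$z_threshold,
                               method = config$association_method)
    logf("network: %d retained edges", nrow(net))

    stage <- "communities"
    partition <- detect_communities(net,
                                    seed = derive_seed(config$seed, "infomap"),
                                    method = config$community_method)
    class_grns <- assign_subnetworks(partition, templates, net,
                                     top_k = config$top_k,
                                     alpha = config$alpha)

    stage <- "train"
    model <- train_classifiers(expr_train, labels[split$train], class_grns,
                               templates, ntree = config$ntree,
                               top_k = config$top_k, seed = config$seed)
    class_grns <- model$class_grns

    stage <- "validate"
    eval <- evaluate_all(model, expr_valid, labels[split$validation],
                         n_boot = config$n_boot, seed = config$seed)
    write_tsv_stamped(as.data.frame(eval$scores),
                      file.path(out_dir, "classification_scores.tsv"),
                      hash, row_names = TRUE)
    curves <- do.call(rbind, lapply(names(eval$curves), function(cl)
      cbind(class = cl, as.data.frame(eval$curves[[cl]]))))
    write_tsv_stamped(curves, file.path(out_dir, "pr_curves.tsv"), hash)
    jsonlite::write_json(
      list(config_hash = hash, mean_aupr = eval$mean_aupr,
           mean_auroc = eval$mean_auroc, per_class = eval$auc),
      file.path(out_dir, "auc_summary.json"), auto_unbox = TRUE, digits = NA)

    stage <- "grn-metrics"
    metrics <- grn_metrics(class_grns)
    write_tsv_stamped(metrics$summary, file.path(out_dir, "grn_size.tsv"),
                      hash)
    write_tsv_stamped(metrics$targets_per_tf,
                      file.path(out_dir, "targets_per_tf.tsv"), hash)
    write_tsv_stamped(metrics$regulators_per_target,
                      file.path(out_dir, "regulators_per_target.tsv"), hash)
    for (cl in names(class_grns))
      export_network(class_grns[[cl]],
                     file.path(out_dir, sprintf("grn_%s.graphml", cl)), hash)

    stage <- "status"
    stats <- fit_training_stats(expr_train, labels[split$train], class_grns,
                                z_cap = config$z_cap,
                                sigma_floor_frac = config$sigma_floor_frac)
    status_rows <- list()
    queries <- list()
    if (simulated && config$n_query_per_class > 0) {
      for (cl in gs$truth$classes)
        queries[[cl]] <- normalize_total(
          simulate_query(sc, gs$truth, cl, attenuation = config$attenuation,
                         n = config$n_query_per_class,
                         seed = derive_seed(config$seed, paste0("q:", cl))),
          scale = config$normalize_scale)
    } else if (!is.null(config$query_expression_path)) {
      q <- normalize_total(read_expression(config$query_expression_path),
                           scale = config$normalize_scale)
      queries[["query"]] <- q
    }
    for (cl in names(stats$per_class)) {
      s_train <- grn_status(expr_train[, labels[split$train] == cl,
                                       drop = FALSE], cl, stats)
      status_rows[[length(status_rows) + 1]] <-
        data.frame(sample = names(s_train), class = cl,
                   status_percent = unname(s_train), group = "training")
      s_valid <- grn_status(expr_valid[, labels[split$validation] == cl,
                                       drop = FALSE], cl, stats)
      status_rows[[length(status_rows) + 1]] <-
        data.frame(sample = names(s_valid), class = cl,
                   status_percent = unname(s_valid), group = "validation")
      for (qn in names(queries)) {
        if (simulated && qn != cl) next  # matched-type queries only
        s_q <- grn_status(queries[[qn]], cl, stats)
        status_rows[[length(status_rows) + 1]] <-
          data.frame(sample = names(s_q), class = cl,
                     status_percent = unname(s_q),
                     group = paste0("query_", qn))
      }
    }
    status_table <- do.call(rbind, status_rows)
    write_tsv_stamped(status_table, file.path(out_dir, "grn_status.tsv"),
                      hash)

    stage <- "nis"
    nis_rows <- list()
    for (cl in names(stats$per_class)) {
      q <- if (simulated) queries[[cl]] else queries[["query"]]
      if (is.null(q)) next
      tbl <- suppressWarnings(
        network_influence(q, cl, class_grns[[cl]], stats))
      if (nrow(tbl) > 0) nis_rows[[length(nis_rows) + 1]] <- tbl
    }
    if (length(nis_rows) > 0)
      write_tsv_stamped(do.call(rbind, nis_rows),
                        file.path(out_dir, "nis.tsv"), hash)

    logf("done")
    list(hash = hash, sample_table = sample_table, split = split,
         templates = templates, network = net, partition = partition,
         class_grns = class_grns, model = model, evaluation = eval,
         metrics = metrics, stats = stats, status = status_table,
         out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed (config %s): %s",
                 stage, hash, conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
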