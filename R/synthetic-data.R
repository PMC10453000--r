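#' Simulation configuration for a multi-class expression corpus
#'
#' Describes the stated world the generator emulates: a training corpus of
#' `n_classes` cancer types, each driven by `n_tfs_per_class` transcription
#' factor (TF) hubs whose `targets_per_tf` targets are co-elevated by a
#' multiplicative `hub_effect` in samples of that class, on top of
#' `n_background_genes` unregulated genes. Intensities are log-normal around a
#' positive `baseline`, mimicking microarray scale: value =
#' baseline * effect * exp(N(0, noise_sd^2)).
#'
#' @param n_classes number of classes (cancer types)
#' @param n_tfs_per_class TF hubs planted per class
#' @param targets_per_tf distinct target genes per TF (disjoint across TFs)
#' @param n_background_genes unregulated genes
#' @param samples_per_class training samples per class
#' @param hub_effect fold-change (>= 1) applied to a class's TFs and their
#'   targets in samples of that class
#' @param noise_sd standard deviation of log-scale noise (>= 0)
#' @param decoy_pairs gold-standard TF->target pairs drawn among background
#'   genes, with no planted co-regulation
#' @param baseline per-gene baseline intensity (positive scalar)
#' @param seed integer seed; all generator randomness derives from it
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_classes = 17, n_tfs_per_class = 5, targets_per_tf = 10,
                       n_background_genes = 1000, samples_per_class = 20,
                       hub_effect = 4, noise_sd = 0.5, decoy_pairs = 100,
                       baseline = 100, seed = 1) {
  counts <- c(n_classes = n_classes, n_tfs_per_class = n_tfs_per_class,
              targets_per_tf = targets_per_tf,
              n_background_genes = n_background_genes,
              samples_per_class = samples_per_class, decoy_pairs = decoy_pairs)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("all counts must be non-negative integers")
  if (hub_effect < 1) stop("hub_effect must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (baseline <= 0) stop("baseline must be positive")
  if (decoy_pairs > 0 && n_background_genes < 2)
    stop("decoy_pairs require at least 2 background genes")
  structure(c(as.list(counts), list(hub_effect = hub_effect,
                                    noise_sd = noise_sd, baseline = baseline,
                                    seed = as.integer(seed))),
            class = "sim_config")
}

#' Generate a gold standard and the planted ground truth
#'
#' Emits every planted class-TF -> target pair plus exactly `decoy_pairs`
#' pairs among background genes (true negatives for edge thresholding).
#' Deterministic under `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list with `gold_standard` (data.frame tf, target) and `truth`
#'   (class->TF map, TF->target map, per-gene baseline, gene/class universe)
#' @export
generate_gold_standard <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  classes <- sprintf("class%02d", seq_len(config$n_classes))
  class_tfs <- list(); tf_targets <- list()
  pairs_tf <- character(0); pairs_tg <- character(0)
  for (ci in seq_along(classes)) {
    tfs <- sprintf("TF_c%02d_%02d", ci, seq_len(config$n_tfs_per_class))
    class_tfs[[classes[ci]]] <- tfs
    for (ti in seq_along(tfs)) {
      tg <- if (config$targets_per_tf > 0)
        sprintf("TG_c%02d_%02d_%03d", ci, ti, seq_len(config$targets_per_tf))
      else character(0)
      tf_targets[[tfs[ti]]] <- tg
      pairs_tf <- c(pairs_tf, rep(tfs[ti], length(tg)))
      pairs_tg <- c(pairs_tg, tg)
    }
  }
  background <- if (config$n_background_genes > 0)
    sprintf("BG_%04d", seq_len(config$n_background_genes)) else character(0)

  if (config$decoy_pairs > 0) {
    set.seed(derive_seed(config$seed, "decoys"))
    max_pairs <- length(background) * (length(background) - 1L)
    if (config$decoy_pairs > max_pairs)
      stop("not enough background genes for the requested decoy pairs")
    seen <- character(0)
    while (length(seen) < config$decoy_pairs) {
      need <- config$decoy_pairs - length(seen)
      a <- sample(background, need, replace = TRUE)
      b <- sample(background, need, replace = TRUE)
      ok <- a != b
      seen <- unique(c(seen, paste(a[ok], b[ok], sep = "\r")))
    }
    seen <- seen[seq_len(config$decoy_pairs)]
    dec <- do.call(rbind, strsplit(seen, "\r", fixed = TRUE))
    pairs_tf <- c(pairs_tf, dec[, 1]); pairs_tg <- c(pairs_tg, dec[, 2])
  }
  genes <- c(unlist(class_tfs, use.names = FALSE),
             unlist(tf_targets, use.names = FALSE), background)
  truth <- list(classes = classes, class_tfs = class_tfs,
                tf_targets = tf_targets, background = background,
                genes = genes,
                baseline = setNames(rep(config$baseline, length(genes)), genes))
  gold <- data.frame(tf = pairs_tf, target = pairs_tg,
                     stringsAsFactors = FALSE)
  list(gold_standard = gold, truth = truth)
}

# genes belonging to a class's planted regulatory program (TFs + their targets)
class_genes <- function(truth, class) {
  tfs <- truth$class_tfs[[class]]
  if (is.null(tfs)) stop(sprintf("unknown class '%s'", class))
  c(tfs, unlist(truth$tf_targets[tfs], use.names = FALSE))
}

# Draw one block of samples under the generative law: baseline * effect * lognoise
sim_block <- function(truth, config, effect_genes, n, prefix) {
  genes <- truth$genes
  eff <- ifelse(genes %in% effect_genes, config$hub_effect, 1)
  noise <- matrix(exp(rnorm(length(genes) * n, sd = config$noise_sd)),
                  nrow = length(genes))
  m <- truth$baseline[genes] * eff * noise
  dimnames(m) <- list(genes, sprintf("%s_%02d", prefix, seq_len(n)))
  m
}

#' Simulate the training corpus
#'
#' Builds the gene-by-sample intensity matrix and its sample metatable. In
#' samples of class c the TFs of c and their targets have expected intensity
#' baseline*hub_effect; all other genes sit at baseline. All intensities are
#' strictly positive.
#'
#' @param config a [sim_config()]
#' @param truth ground truth from [generate_gold_standard()]
#' @return list with `sample_table` (sample_id, file_name, description) and
#'   `expr` (genes x samples matrix)
#' @export
simulate_corpus <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "corpus"))
  blocks <- list(); ann <- character(0)
  for (cl in truth$classes) {
    b <- sim_block(truth, config, class_genes(truth, cl),
                   config$samples_per_class, cl)
    blocks[[cl]] <- b
    ann <- c(ann, rep(cl, ncol(b)))
  }
  expr <- do.call(cbind, blocks)
  st <- data.frame(sample_id = colnames(expr),
                   file_name = paste0(colnames(expr), ".CEL"),
                   description = ann, stringsAsFactors = FALSE)
  list(sample_table = st, expr = expr)
}

#' Simulate query samples with a partially established class program
#'
#' A random subset of the class's GRN genes (fraction `attenuation`, chosen
#' once per call) receives the class `hub_effect`; the remaining class genes
#' stay at baseline. `attenuation = 1` reproduces the training generative law
#' for the class; `attenuation = 0` follows the background law.
#'
#' @param config a [sim_config()]
#' @param truth ground truth from [generate_gold_standard()]
#' @param target_class class label present in `truth`
#' @param attenuation fraction in \[0, 1\] of the class program expressed
#' @param n number of query samples
#' @param seed integer seed
#' @return genes x samples matrix
#' @export
simulate_query <- function(config, truth, target_class, attenuation = 1,
                           n = 10, seed = 1) {
  if (!target_class %in% truth$classes)
    stop(sprintf("unknown class '%s'", target_class))
  if (attenuation < 0 || attenuation > 1) stop("attenuation must be in [0,1]")
  set.seed(derive_seed(seed, paste0("query:", target_class)))
  cg <- class_genes(truth, target_class)
  k <- round(attenuation * length(cg))
  on_genes <- if (k > 0) sample(cg, k) else character(0)
  sim_block(truth, config, on_genes, n, paste0("query_", target_class))
}

#' Simulate a query in which one TF hub is silenced
#'
#' Generates matched-class query samples (attenuation 1) except that the named
#' TF and all of its targets are held at baseline — the planted perturbation
#' used to validate network-influence ranking.
#'
#' @inheritParams simulate_query
#' @param tf a TF of `target_class`
#' @export
simulate_silenced_query <- function(config, truth, target_class, tf,
                                    n = 10, seed = 1) {
  if (!tf %in% truth$class_tfs[[target_class]])
    stop(sprintf("'%s' is not a TF of %s", tf, target_class))
  set.seed(derive_seed(seed, paste0("silenced:", target_class, ":", tf)))
  on_genes <- setdiff(class_genes(truth, target_class),
                      c(tf, truth$tf_targets[[tf]]))
  sim_block(truth, config, on_genes, n, paste0("query_", target_class))
}

#' Survival simulation configuration
#'
#' @param n_patients cohort size (>= 2)
#' @param beta log hazard ratio of the high-expression group
#' @param censor_rate expected fraction censored, in \[0, 1)
#' @param true_cutoff expression threshold defining the high group
#' @param h0 baseline hazard of the low group
#' @param seed integer seed
#' @export
survival_sim_config <- function(n_patients = 200, beta = 1, censor_rate = 0.2,
                                true_cutoff = 100, h0 = 0.1, seed = 1) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0,1)")
  if (h0 <= 0) stop("h0 must be positive")
  structure(list(n_patients = as.integer(n_patients), beta = beta,
                 censor_rate = censor_rate, true_cutoff = true_cutoff,
                 h0 = h0, seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate a survival cohort with a step expression effect
#'
#' Expression is log-normal (median `true_cutoff` by default construction is
#' NOT imposed; the cutoff is a free threshold). Event times are exponential
#' with hazard `h0 * exp(beta * 1\{expr > true_cutoff\})`; censoring times are
#' independent exponentials with rate `h0 * censor_rate / (1 - censor_rate)`,
#' so the expected censored fraction equals `censor_rate` when `beta = 0`.
#'
#' @param config a [survival_sim_config()]
#' @return data.frame (patient_id, time, event, expression)
#' @export
simulate_survival <- function(config) {
  stopifnot(inherits(config, "survival_sim_config"))
  set.seed(derive_seed(config$seed, "survival"))
  n <- config$n_patients
  expr <- exp(rnorm(n, mean = log(100), sd = 0.5)) # log-normal intensities
  hi <- as.numeric(expr > config$true_cutoff)
  haz <- config$h0 * exp(config$beta * hi)
  t_event <- rexp(n, rate = haz)
  if (config$censor_rate > 0) {
    c_rate <- config$h0 * config$censor_rate / (1 - config$censor_rate)
    t_cens <- rexp(n, rate = c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  data.frame(patient_id = sprintf("pt_%04d", seq_len(n)),
             time = time, event = event, expression = expr,
             stringsAsFactors = FALSE)
}

## ---- serialization -------------------------------------------------------

#' Write / read the standard file formats of the pipeline
#'
#' SampleTable as CSV (sample_id, file_name, description); expression as TSV
#' with genes in rows and sample ids in the header; gold standard as
#' two-column TSV (tf, target); survival cohorts as CSV
#' (patient_id, time, event, expression); ground truth as YAML.
#'
#' @param x object to write
#' @param path file path
#' @name serialization
NULL

#' @rdname serialization
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname serialization
#' @export
write_gold_standard <- function(x, path) {
  write.table(x[, c("tf", "target")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
read_gold_standard <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(df)))
    stop("gold standard must have columns 'tf' and 'target'")
  df
}

#' @rdname serialization
#' @export
write_survival_data <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
read_survival_data <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "event", "expression")
  if (!all(need %in% names(df)))
    stop("survival data must have columns time, event, expression")
  df
}

#' @rdname serialization
#' @export
write_ground_truth <- function(x, path) {
  yaml::write_yaml(list(classes = x$classes,
                        class_tfs = x$class_tfs,
                        tf_targets = x$tf_targets,
                        background = x$background,
                        baseline = as.list(x$baseline)), path)
  invisible(path)
}
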