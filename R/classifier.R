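#' Stratified half split of the training table
#'
#' Divides the samples of every class 50/50 into a training half and a
#' validation half; odd class counts put the extra sample in training.
#' Deterministic under `seed`.
#'
#' @param sample_table data.frame with `sample_id` and `description` (class)
#' @param seed integer seed
#' @return list with `train` and `validation` sample-id vectors
#' @export
split_half <- function(sample_table, seed = 1) {
  tab <- table(sample_table$description)
  if (any(tab < 2))
    stop(sprintf("singleton class: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  set.seed(derive_seed(seed, "split"))
  train <- character(0)
  for (cl in sort(names(tab))) {
    ids <- sample_table$sample_id[sample_table$description == cl]
    n_train <- ceiling(length(ids) / 2)
    train <- c(train, sample(ids, n_train))
  }
  list(train = sort(train),
       validation = sort(setdiff(sample_table$sample_id, train)))
}

#' Train one-vs-rest random forest classifiers
#'
#' One balanced random forest per class. The feature set of a class is its
#' GRN genes united with its top `top_k` template genes (the fallback when a
#' GRN came out empty). Per-gene importances (mean decrease in Gini) are
#' stored and propagated to the class GRN weights w_g, normalized to sum to 1
#' over the GRN genes. Deterministic under `seed`.
#'
#' @param expr_train gene-by-sample training matrix (normalized)
#' @param labels class per training sample
#' @param class_grns named list of `class_grn` (one per class, possibly empty)
#' @param templates gene-by-class template scores (for the feature fallback)
#' @param ntree trees per forest (default 1000)
#' @param top_k template genes per class added to the features (default 100)
#' @param mtry features per split; default floor(sqrt(p))
#' @param seed integer seed
#' @return object of class `grn_classifier`: per class forest, feature list,
#'   importances; `class_grns` with importance weights filled in
#' @export
train_classifiers <- function(expr_train, labels, class_grns, templates,
                              ntree = 1000, top_k = 100, mtry = NULL,
                              seed = 1) {
  stopifnot(is.matrix(expr_train), length(labels) == ncol(expr_train))
  classes <- names(class_grns)
  models <- list()
  for (cl in classes) {
    grn_genes <- intersect(class_grns[[cl]]$genes, rownames(expr_train))
    ord <- order(templates[, cl], decreasing = TRUE)
    top_genes <- rownames(templates)[ord[seq_len(min(top_k, nrow(templates)))]]
    features <- sort(unique(c(grn_genes, intersect(top_genes,
                                                   rownames(expr_train)))))
    if (length(features) == 0)
      stop(sprintf("no features available for class %s", cl))
    X <- t(expr_train[features, , drop = FALSE])
    y <- as.integer(labels == cl)
    if (all(y == 0)) stop(sprintf("no training samples for class %s", cl))
    m <- if (is.null(mtry)) max(1L, floor(sqrt(length(features)))) else mtry
    set.seed(derive_seed(seed, paste0("rf:", cl)))
    fit <- .rf_train(X, y, as.integer(ntree), as.integer(m), 1L)
    imp <- setNames(as.numeric(fit$importance), features)
    models[[cl]] <- list(forest = fit, features = features, importance = imp)
    # propagate to GRN weights
    g <- class_grns[[cl]]$genes
    if (length(g) > 0) {
      w <- imp[g]
      w[is.na(w)] <- 0
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(g), length(g))
      class_grns[[cl]]$importance <- setNames(w, g)
    }
  }
  structure(list(models = models, classes = classes,
                 class_grns = class_grns, ntree = ntree, seed = seed),
            class = "grn_classifier")
}

#' @export
print.grn_classifier <- function(x, ...) {
  cat(sprintf("<grn_classifier> %d classes, %d trees/forest\n",
              length(x$classes), x$ntree))
  invisible(x)
}

#' Score samples against every class classifier
#'
#' The classification score of a sample for a class is the fraction of that
#' class's trees voting for it — the heatmap entries of the trained model's
#' validation and query displays. Feature genes missing from the query matrix
#' are imputed at 0 with a warning.
#'
#' @param model a `grn_classifier`
#' @param expr gene-by-sample matrix (normalized like the training data)
#' @return class-by-sample score matrix, entries in \[0, 1\]
#' @export
classify <- function(model, expr) {
  stopifnot(inherits(model, "grn_classifier"), is.matrix(expr))
  scores <- matrix(NA_real_, nrow = length(model$classes), ncol = ncol(expr),
                   dimnames = list(model$classes, colnames(expr)))
  warned <- FALSE
  for (cl in model$classes) {
    feats <- model$models[[cl]]$features
    missing <- setdiff(feats, rownames(expr))
    if (length(missing) > 0 && !warned) {
      warning(sprintf("%d feature gene(s) absent from query; imputed at 0",
                      length(missing)))
      warned <- TRUE
    }
    X <- matrix(0, nrow = ncol(expr), ncol = length(feats),
                dimnames = list(colnames(expr), feats))
    present <- intersect(feats, rownames(expr))
    X[, present] <- t(expr[present, , drop = FALSE])
    scores[cl, ] <- .rf_predict(model$models[[cl]]$forest, X)
  }
  scores
}

#' Precision-sensitivity curve and its area
#'
#' At every distinct score cutoff, samples with score >= cutoff are called
#' positive; precision = TP/(TP+FP) (1 by convention when nothing is called)
#' and sensitivity = TP/(TP+FN). The area is the step-wise integral of
#' precision over sensitivity, anchored at (sensitivity 0, precision 1).
#'
#' @param scores numeric scores for one class
#' @param truth binary labels (1 = positive); at least one positive required
#' @return object of class `pr_curve`: data.frame
#'   (cutoff, precision, sensitivity) ordered by decreasing cutoff, with
#'   attribute `auc`
#' @export
pr_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  n_pos <- sum(truth == 1)
  if (n_pos == 0) stop("no positive samples in truth")
  cutoffs <- sort(unique(scores), decreasing = TRUE)
  prec <- sens <- numeric(length(cutoffs))
  for (k in seq_along(cutoffs)) {
    called <- scores >= cutoffs[k]
    tp <- sum(called & truth == 1)
    prec[k] <- if (sum(called) == 0) 1 else tp / sum(called)
    sens[k] <- tp / n_pos
  }
  curve <- data.frame(cutoff = cutoffs, precision = prec, sensitivity = sens)
  auc <- sum(diff(c(0, sens)) * prec)
  structure(curve, class = c("pr_curve", "data.frame"), auc = auc)
}

#' @rdname pr_curve
#' @param x a `pr_curve`
#' @export
pr_auc <- function(x) attr(x, "auc")

# area under the ROC curve (Mann-Whitney form), reported alongside AUPR
roc_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Evaluate all class classifiers on validation data
#'
#' Scores the validation half, computes each class's precision-sensitivity
#' curve and area, the mean area across classes, and a seeded percentile
#' bootstrap confidence interval per class (resampling validation samples).
#' The area under the ROC curve is reported alongside.
#'
#' @param model a `grn_classifier`
#' @param expr_valid gene-by-sample validation matrix
#' @param labels_valid class per validation sample
#' @param n_boot bootstrap draws (default 200)
#' @param seed integer seed
#' @param conf confidence level (default 0.95)
#' @return list: `curves` (per class `pr_curve`), `auc` (per-class data.frame
#'   with aupr, auroc, ci bounds), `mean_aupr`, `mean_auroc`, `scores`
#' @export
evaluate_all <- function(model, expr_valid, labels_valid, n_boot = 200,
                         seed = 1, conf = 0.95) {
  scores <- classify(model, expr_valid)
  classes <- model$classes
  if (any(!classes %in% labels_valid))
    stop("validation is empty for at least one class")
  curves <- list()
  aupr <- auroc <- lo <- hi <- numeric(length(classes))
  set.seed(derive_seed(seed, "bootstrap"))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    truth <- as.integer(labels_valid == cl)
    curves[[cl]] <- pr_curve(scores[cl, ], truth)
    aupr[k] <- pr_auc(curves[[cl]])
    auroc[k] <- roc_auc(scores[cl, ], truth)
    boot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample(length(truth), replace = TRUE)
      while (sum(truth[idx]) == 0)  # resample until a positive is drawn
        idx <- sample(length(truth), replace = TRUE)
      boot[b] <- pr_auc(pr_curve(scores[cl, idx], truth[idx]))
    }
    qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    lo[k] <- qs[1]; hi[k] <- qs[2]
  }
  list(curves = curves,
       auc = data.frame(class = classes, aupr = aupr, auroc = auroc,
                        ci_lower = lo, ci_upper = hi,
                        row.names = NULL, stringsAsFactors = FALSE),
       mean_aupr = mean(aupr), mean_auroc = mean(auroc), scores = scores)
}
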