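#' Fit per-class training statistics for GRN status
#'
#' For every class with a non-empty GRN: the mean and standard deviation of
#' each GRN gene over that class's training samples (sd floored at
#' `sigma_floor_frac` of the gene's training mean), the classifier importance
#' weights w_g renormalized to sum to 1, and the class's mean raw status m_c
#' over its own training samples. m_c is the standardization constant that
#' makes training samples average 100%.
#'
#' With few training samples per class, raw per-gene standard deviations are
#' noisy and bias out-of-sample z-scores upward; unless `moderate_sigma =
#' FALSE`, per-gene variances are therefore shrunk toward the class trend on
#' the squared-coefficient-of-variation scale by empirical-Bayes moderation
#' (the standard small-n device of the microarray literature): the prior
#' degrees of freedom are estimated from how much the observed spread of
#' log-CV^2 exceeds its chi-squared sampling expectation, so homogeneous
#' variance structures get strong pooling and heterogeneous ones keep their
#' per-gene estimates.
#'
#' @param expr_train gene-by-sample training matrix (normalized)
#' @param labels class per training sample
#' @param class_grns named list of `class_grn` with importances filled in
#' @param z_cap z-score cap (default 3)
#' @param sigma_floor_frac sd floor as a fraction of the gene mean
#'   (default 1e-3)
#' @param moderate_sigma shrink per-gene variances toward the class trend
#'   (default TRUE)
#' @return object of class `training_stats`
#' @export
fit_training_stats <- function(expr_train, labels, class_grns, z_cap = 3,
                               sigma_floor_frac = 1e-3,
                               moderate_sigma = TRUE) {
  stopifnot(is.matrix(expr_train), length(labels) == ncol(expr_train))
  stats <- list()
  for (cl in names(class_grns)) {
    grn <- class_grns[[cl]]
    genes <- intersect(grn$genes, rownames(expr_train))
    if (length(genes) == 0) {
      warning(sprintf("empty GRN for class %s; stats omitted", cl))
      next
    }
    cols <- labels == cl
    if (sum(cols) < 2)
      stop(sprintf("class %s has < 2 training samples", cl))
    sub <- expr_train[genes, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sigma <- apply(sub, 1, sd)
    if (moderate_sigma && length(genes) > 1) {
      cv2 <- (sigma / pmax(mu, .Machine$double.eps))^2
      cv2_mod <- squeeze_var(cv2, df = sum(cols) - 1)
      sigma <- pmax(mu, 0) * sqrt(cv2_mod)
    }
    sigma <- pmax(sigma, sigma_floor_frac * pmax(mu, .Machine$double.eps))
    w <- grn$importance[genes]
    w[is.na(w)] <- 0
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(genes), length(genes))
    st <- list(class = cl, genes = genes, mu = mu, sigma = sigma,
               w = setNames(w, genes), z_cap = z_cap)
    # raw status of the class's own training samples -> standardization m_c
    raw <- apply(sub, 2, function(x) raw_status(x, st))
    st$m_c <- mean(raw)
    stats[[cl]] <- st
  }
  structure(list(per_class = stats, z_cap = z_cap), class = "training_stats")
}

# Empirical-Bayes variance moderation (Smyth-style squeeze): shrinks sample
# variances s2 at `df` toward a common prior; the prior df is read off the
# excess of var(log s2) over its chi-squared sampling value trigamma(df/2).
squeeze_var <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(s2)
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {         # no excess: full pooling
    s0 <- exp(mean(e))
    out <- s2; out[ok] <- s0; out[!ok] <- s0
    return(out)
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  out <- s2
  out[ok] <- (d0 * s0 + df * s2[ok]) / (d0 + df)
  out[!ok] <- s0
  out
}

# Newton inversion of trigamma, as used for moderated variance prior df.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

# weighted capped-z proximity of one sample (named vector over stats genes)
raw_status <- function(x, st) {
  z <- (x - st$mu) / st$sigma
  z <- pmin(pmax(z, -st$z_cap), st$z_cap)
  s <- (st$z_cap - abs(z)) / st$z_cap
  sum(st$w * s)
}

#' GRN status of samples against a class
#'
#' Each GRN gene's expression is converted to a z-score against the class's
#' training distribution, capped at `z_cap`, and mapped to a proximity score
#' s_g = (z_cap - |z|)/z_cap in \[0, 1\]; the importance-weighted mean of the
#' s_g is divided by the class's training mean m_c and scaled to percent, so
#' the class's own training samples average 100. Genes missing from the
#' matrix count as maximally dysregulated (s_g = 0) with a warning.
#'
#' @param expr gene-by-sample matrix (normalized like training)
#' @param class class label with fitted stats
#' @param stats a `training_stats`
#' @return named numeric vector: status percentage per sample (>= 0)
#' @export
grn_status <- function(expr, class, stats) {
  stopifnot(inherits(stats, "training_stats"), is.matrix(expr))
  st <- stats$per_class[[class]]
  if (is.null(st)) stop(sprintf("no fitted stats for class %s", class))
  missing <- setdiff(st$genes, rownames(expr))
  if (length(missing) > 0)
    warning(sprintf("%d GRN gene(s) missing; treated as fully dysregulated",
                    length(missing)))
  present <- intersect(st$genes, rownames(expr))
  out <- vapply(seq_len(ncol(expr)), function(j) {
    x <- setNames(rep(NA_real_, length(st$genes)), st$genes)
    x[present] <- expr[present, j]
    z <- (x - st$mu) / st$sigma
    z[is.na(z)] <- st$z_cap  # missing gene: maximal dysregulation
    z <- pmin(pmax(z, -st$z_cap), st$z_cap)
    s <- (st$z_cap - abs(z)) / st$z_cap
    100 * sum(st$w * s) / st$m_c
  }, 0)
  setNames(out, colnames(expr))
}

#' Per-group GRN status summary
#'
#' Mean and standard deviation of status per sample group (training reference
#' groups average 100 by construction).
#'
#' @param status named status vector from [grn_status()]
#' @param groups group label per sample (same order)
#' @return data.frame (group, n, mean, sd)
#' @export
status_report <- function(status, groups) {
  stopifnot(length(status) == length(groups))
  gs <- sort(unique(groups))
  data.frame(group = gs,
             n = vapply(gs, function(g) sum(groups == g), 0L),
             mean = vapply(gs, function(g) mean(status[groups == g]), 0),
             sd = vapply(gs, function(g) {
               v <- status[groups == g]
               if (length(v) < 2) 0 else sd(v)
             }, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
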