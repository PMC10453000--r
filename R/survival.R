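#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival estimate: at each distinct event time t_i with d_i
#' events among n_i at risk, the survival probability multiplies by
#' (1 - d_i/n_i). Starts at 1 and is non-increasing; censoring only reduces
#' the risk set.
#'
#' @param time positive follow-up times
#' @param event event indicator (1 = event, 0 = censored)
#' @return data.frame (time, n_risk, n_event, survival) at distinct event
#'   times, ordered by time
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stop("empty input")
  stopifnot(all(time > 0), all(event %in% c(0, 1)),
            length(time) == length(event))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  if (length(ts) == 0)
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0)))
  n_risk <- vapply(ts, function(t) sum(time >= t), 0L)
  n_event <- vapply(ts, function(t) sum(time == t & event == 1), 0L)
  data.frame(time = ts, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group 1 are compared to
#' the expectation under the hypergeometric law of the pooled risk set (ties
#' pooled); chi-squared = (sum O - sum E)^2 / sum V with 1 df.
#'
#' @param time positive follow-up times
#' @param event event indicator (1 = event, 0 = censored)
#' @param group binary group membership (two non-empty groups required)
#' @return list (chisq, p)
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2) stop("exactly two non-empty groups required")
  if (sum(event) < 1) stop("at least one event required")
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Single-covariate Cox proportional hazards fit for a binary split
#'
#' Maximizes the partial likelihood with Breslow tie handling by Newton
#' iteration. The score test at beta = 0 equals the log-rank chi-squared on
#' tie-free data. Monotone likelihood (a group without events) is signaled.
#'
#' @param time positive follow-up times
#' @param event event indicator
#' @param group binary covariate (coerced to 0/1; hazard ratio is
#'   exp(beta) of group 1 vs group 0)
#' @param max_iter Newton iterations (default 25)
#' @param tol convergence tolerance on the score (default 1e-9)
#' @return list (hr, beta, se, score_chisq, wald_p, iterations)
#' @export
cox_hr <- function(time, event, group, max_iter = 25, tol = 1e-9) {
  x <- as.numeric(as.integer(factor(group)) - 1L)
  if (length(unique(x)) != 2) stop("exactly two non-empty groups required")
  if (sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0)
    stop("monotone likelihood: one group has no events")
  ts <- sort(unique(time[event == 1]))
  # Breslow log partial likelihood derivatives at beta
  derivs <- function(beta) {
    u <- 0; info <- 0
    r <- exp(beta * x)
    for (t in ts) {
      at_risk <- time >= t
      d <- sum(time == t & event == 1)
      sx <- sum(time == t & event == 1 & x == 1)
      s0 <- sum(r[at_risk])
      s1 <- sum(r[at_risk] * x[at_risk])
      u <- u + (sx - d * s1 / s0)
      info <- info + d * (s1 / s0) * (1 - s1 / s0)
    }
    c(u = u, info = info)
  }
  d0 <- derivs(0)
  score_chisq <- if (d0["info"] > 0) unname(d0["u"]^2 / d0["info"]) else 0
  beta <- 0
  for (it in seq_len(max_iter)) {
    d <- derivs(beta)
    if (d["info"] <= 0) stop("singular information matrix")
    step <- d["u"] / d["info"]
    beta <- beta + step
    if (abs(d["u"]) < tol || abs(step) < tol) break
  }
  d <- derivs(beta)
  if (abs(d["u"]) > 1e-4)
    stop(sprintf("Cox fit did not converge: score %.3g after %d iterations",
                 d["u"], max_iter))
  se <- sqrt(1 / unname(d["info"]))
  list(hr = exp(beta), beta = unname(beta), se = se,
       score_chisq = score_chisq,
       wald_p = 2 * stats::pnorm(-abs(beta / se)), iterations = it)
}

# Benjamini-Hochberg step-up q-values (monotone adjusted p-values)
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(n / (n:1) * p[ord]))
  q[order(ord)]
}

#' Best-cutoff survival scan between the expression quartiles
#'
#' Candidate cutoffs are all distinct observed expression values strictly
#' between the lower and upper quartiles. Each cutoff's high-vs-low split is
#' tested with the log-rank statistic (the Cox score test at beta = 0, making
#' the scan a Cox-regression assessment of every cutoff); Benjamini-Hochberg
#' q-values are computed across the scan and only cutoffs with q < `fdr` are
#' accepted. Among accepted cutoffs the smallest p wins (ties: smallest
#' cutoff) and its hazard ratio comes from a full Cox fit. When no cutoff
#' passes the gate an explicit no-selection marker is returned.
#'
#' @param dataset data.frame with columns time, event, expression
#' @param fdr acceptance threshold on the BH q-value (default 0.10)
#' @return list with `scan` (cutoff, chisq, p, q, n_low, n_high) and `best`
#'   (list cutoff, p, q, hr, beta — or NULL fields with `selected = FALSE`)
#' @export
scan_cutoffs <- function(dataset, fdr = 0.10) {
  expr <- dataset$expression
  if (length(unique(expr)) < 2) stop("all expression values are identical")
  qs <- quantile(expr, c(0.25, 0.75), names = FALSE)
  cand <- sort(unique(expr[expr > qs[1] & expr < qs[2]]))
  if (length(cand) == 0)
    stop("no candidate cutoff strictly between the expression quartiles")
  rows <- lapply(cand, function(ct) {
    hi <- expr > ct
    lr <- logrank_test(dataset$time, dataset$event, hi)
    data.frame(cutoff = ct, chisq = lr$chisq, p = lr$p,
               n_low = sum(!hi), n_high = sum(hi))
  })
  scan <- do.call(rbind, rows)
  scan$q <- bh_adjust(scan$p)
  scan <- scan[, c("cutoff", "chisq", "p", "q", "n_low", "n_high")]
  accepted <- which(scan$q < fdr)
  if (length(accepted) == 0) {
    best <- list(selected = FALSE, cutoff = NULL, p = NULL, q = NULL,
                 hr = NULL, beta = NULL)
  } else {
    i <- accepted[order(scan$p[accepted], scan$cutoff[accepted])][1]
    fit <- cox_hr(dataset$time, dataset$event, expr > scan$cutoff[i])
    best <- list(selected = TRUE, cutoff = scan$cutoff[i], p = scan$p[i],
                 q = scan$q[i], hr = fit$hr, beta = fit$beta)
  }
  list(scan = scan, best = best)
}
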