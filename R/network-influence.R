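#' Network influence scores of a class GRN's transcription factors
#'
#' Ranks the TFs of a class GRN by how strongly their own dysregulation and
#' that of their targets separates a query group from the class training
#' distribution. For TF t:
#'
#'   NIS(t) = w_t * zbar_t + sum over targets g of w_g * zbar_g * s(t, g)
#'
#' where zbar is the mean capped z-score of the query group against the class
#' training distribution, w the classifier importance weights, and s(t, g)
#' the sign of the training correlation on the edge. The most negative NIS
#' marks the TF whose subnetwork is most under-established in the query;
#' the table is sorted ascending, ties broken by TF name.
#'
#' @param query_expr gene-by-sample query matrix (normalized like training)
#' @param class class label
#' @param class_grn the class's `class_grn` (provides edges and signs)
#' @param stats fitted `training_stats`
#' @param per_sample if TRUE, return one NIS table per query sample instead
#'   of the group-mean table
#' @return data.frame (class, tf, nis, rank); empty with a warning when the
#'   GRN has no TFs
#' @export
network_influence <- function(query_expr, class, class_grn, stats,
                              per_sample = FALSE) {
  st <- stats$per_class[[class]]
  if (is.null(st)) stop(sprintf("no fitted stats for class %s", class))
  edges <- class_grn$edges
  tfs <- sort(unique(edges$tf))
  if (length(tfs) == 0) {
    warning(sprintf("class %s GRN has no TFs", class))
    return(data.frame(class = character(0), tf = character(0),
                      nis = numeric(0), rank = integer(0)))
  }
  zbar_of <- function(cols) {
    x <- matrix(NA_real_, nrow = length(st$genes), ncol = length(cols),
                dimnames = list(st$genes, NULL))
    present <- intersect(st$genes, rownames(query_expr))
    x[present, ] <- query_expr[present, cols, drop = FALSE]
    z <- (x - st$mu) / st$sigma
    z[is.na(z)] <- st$z_cap
    z <- pmin(pmax(z, -st$z_cap), st$z_cap)
    rowMeans(z)
  }
  nis_from_z <- function(zbar) {
    vapply(tfs, function(t) {
      v <- if (t %in% names(st$w)) st$w[t] * zbar[t] else 0
      e <- edges[edges$tf == t, , drop = FALSE]
      g <- intersect(e$target, names(zbar))
      if (length(g) > 0) {
        sgn <- e$sign[match(g, e$target)]
        v <- v + sum(st$w[g] * zbar[g] * sgn, na.rm = TRUE)
      }
      unname(v)
    }, 0)
  }
  make_table <- function(nis, sample_id = NULL) {
    ord <- order(nis, tfs)  # ascending, ties by TF name
    out <- data.frame(class = class, tf = tfs[ord], nis = nis[ord],
                      rank = seq_along(tfs), row.names = NULL,
                      stringsAsFactors = FALSE)
    if (!is.null(sample_id)) out <- cbind(sample_id = sample_id, out)
    out
  }
  if (per_sample) {
    do.call(rbind, lapply(seq_len(ncol(query_expr)), function(j) {
      make_table(nis_from_z(zbar_of(j)),
                 colnames(query_expr)[j] %||% as.character(j))
    }))
  } else {
    make_table(nis_from_z(zbar_of(seq_len(ncol(query_expr)))))
  }
}
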