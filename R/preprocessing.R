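#' Collapse probe-level intensities to gene level
#'
#' Probesets mapping to the same gene are averaged (arithmetic mean of probe
#' rows). Probes absent from the map are dropped with a warning.
#'
#' @param probes probe-by-sample non-negative matrix with unique probe rownames
#' @param map data.frame with columns `probe` and `gene` (many probes to one
#'   gene allowed; a probe must not map to more than one gene)
#' @return gene-by-sample matrix
#' @export
collapse_probes <- function(probes, map) {
  stopifnot(is.matrix(probes), !is.null(rownames(probes)))
  if (!all(c("probe", "gene") %in% names(map)))
    stop("map must have columns 'probe' and 'gene'")
  if (anyDuplicated(map$probe))
    stop("a probe maps to more than one gene")
  keep <- rownames(probes) %in% map$probe
  if (!any(keep))
    stop("no probe in the matrix is present in the probe-gene map")
  if (!all(keep))
    warning(sprintf("dropping %d unmapped probe(s)", sum(!keep)))
  probes <- probes[keep, , drop = FALSE]
  gene <- map$gene[match(rownames(probes), map$probe)]
  # group mean by gene: rowsum / group size
  sums <- rowsum(probes, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Total-intensity normalization
#'
#' Divides each array (column) by its total intensity, then rescales to a
#' fixed column total so all downstream statistics see columns of identical
#' mass. Scale-free per column: multiplying an input column by any positive
#' constant leaves its output unchanged.
#'
#' @param expr gene-by-sample non-negative matrix
#' @param scale positive constant column total (default 1e5)
#' @return matrix whose columns each sum to `scale`
#' @export
normalize_total <- function(expr, scale = 1e5) {
  stopifnot(is.matrix(expr), scale > 0)
  tot <- colSums(expr)
  if (any(tot <= 0)) {
    bad <- colnames(expr)[tot <= 0] %||% which(tot <= 0)
    stop(sprintf("zero-total sample(s): %s", paste(bad, collapse = ", ")))
  }
  sweep(expr, 2, tot / scale, "/")
}

#' Robust array-quality filter
#'
#' Flags samples whose log total intensity, or whose median inter-sample
#' Spearman correlation, deviates from the cohort median by more than `k_mad`
#' median absolute deviations. A documented stand-in for platform QC: the
#' criteria are robust and order-invariant, not a reconstruction of any
#' vendor check.
#'
#' @param expr gene-by-sample matrix (>= 3 samples)
#' @param k_mad exclusion threshold in MAD units (default 5)
#' @return list with `kept`, `excluded` (sample names) and `report`
#'   (per-sample metric table)
#' @export
qc_filter <- function(expr, k_mad = 5) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3) stop("qc_filter needs at least 3 samples")
  log_tot <- log(colSums(expr))
  rho <- suppressWarnings(cor(expr, method = "spearman"))
  diag(rho) <- NA
  med_cor <- apply(rho, 2, stats::median, na.rm = TRUE)
  flag_metric <- function(v) {
    ctr <- stats::median(v)
    scl <- stats::mad(v)
    if (scl == 0) return(rep(FALSE, length(v)))
    abs(v - ctr) / scl > k_mad
  }
  bad <- flag_metric(log_tot) | flag_metric(med_cor)
  report <- data.frame(sample_id = colnames(expr) %||% seq_len(ncol(expr)),
                       log_total = log_tot, median_cor = med_cor,
                       excluded = bad, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(kept = report$sample_id[!bad], excluded = report$sample_id[bad],
       report = report)
}

#' @rdname serialization
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(df)))
    stop("probe map must have columns 'probe' and 'gene'")
  df
}
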