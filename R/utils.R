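#' @useDynLib oncogrn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor quantile rnorm runif rexp rbinom sd setNames
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

# Deterministic per-stage seed fan-out from one global seed.
# Keeps derived seeds in [0, 2^31 - 2] so they are valid R integers.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- fnv1a(paste0("seed:", format(seed, scientific = FALSE), "/", stage))
  as.integer(h %% (2^31 - 1))
}

# 32-bit FNV-1a over a character scalar, returned as a double in [0, 2^32).
# All arithmetic stays below 2^53 so doubles are exact.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # (h * 16777619) mod 2^32, split to avoid exceeding 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Hash of a resolved run configuration
#'
#' Canonicalizes a configuration list through YAML and returns an 8-hex-digit
#' FNV-1a hash. Every pipeline output file embeds this hash so artifacts can
#' be traced to the exact configuration that produced them.
#'
#' @param config a named list of parameters
#' @return character scalar, eight hex digits
#' @export
config_hash <- function(config) {
  config <- config[order(names(config))]
  h <- fnv1a(yaml::as.yaml(config))
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# Shared writer: TSV with a '#'-prefixed header line carrying metadata.
write_tsv_stamped <- function(df, path, hash = NULL, row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
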