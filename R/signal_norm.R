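# ChIP-seq track and expression-table normalization: per-bin RPKM,
# genome-wide Z-score, and quantile normalization + log transform.

#' RPKM-normalize binned read counts
#'
#' `rpkm = count / ((bin_width / 1000) * (total_mapped_reads / 1e6))` --
#' reads per kilobase of bin per million mapped reads.
#'
#' @param counts Numeric vector (or list per chromosome) of per-bin read
#'   counts, all >= 0.
#' @param bin_width Bin width in bp.
#' @param total_mapped_reads Library size (> 0).
#' @return RPKM values with the same shape as `counts`.
#' @export
rpkm <- function(counts, bin_width, total_mapped_reads) {
  if (total_mapped_reads <= 0)
    stop("'total_mapped_reads' must be > 0")
  stopifnot(bin_width > 0)
  f <- function(x) {
    if (any(x < 0, na.rm = TRUE)) stop("read counts must be >= 0")
    x / ((bin_width / 1000) * (total_mapped_reads / 1e6))
  }
  if (is.list(counts)) lapply(counts, f) else f(counts)
}

#' Genome-wide Z-score transformation of a signal track
#'
#' Subtracts the genome-wide mean and divides by the genome-wide standard
#' deviation. The population convention (divide by n) is used, so the
#' output has mean 0 and SD exactly 1 over the transformed bins. By
#' default only covered (non-missing) bins enter the statistics and are
#' transformed; with `covered_only = FALSE` missing bins are treated as 0
#' signal first.
#'
#' @param x Numeric vector of per-bin signal (e.g. RPKM); `NA` = missing.
#' @param covered_only Use only non-missing bins (default `TRUE`).
#' @return Z-scored vector (missing bins stay `NA` when `covered_only`).
#' @export
zscore_track <- function(x, covered_only = TRUE) {
  if (!covered_only) x[is.na(x)] <- 0
  v <- x[!is.na(x)]
  if (length(v) < 2) stop("need at least 2 covered bins")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) stop("constant track: standard deviation is 0")
  (x - mu) / sigma
}

#' Quantile-normalize an expression table and log-transform
#'
#' Classic quantile normalization (each rank mapped to the mean of the
#' sorted values across samples; ties averaged), then `log2(x +
#' pseudocount)`. All columns share one sorted value vector afterwards.
#'
#' @param expr Numeric gene x sample matrix, an [expression_matrix()], or a
#'   data.frame coercible to a matrix; >= 2 samples.
#' @param pseudocount Added before the log (default 1).
#' @param log Apply the log2 transform (default `TRUE`).
#' @return Same container type as the input.
#' @export
quantile_normalize_log <- function(expr, pseudocount = 1, log = TRUE) {
  if (inherits(expr, "expression_matrix")) {
    expr$fpkm <- quantile_normalize_log(expr$fpkm, pseudocount, log)
    return(expr)
  }
  m <- as.matrix(expr)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (anyNA(m)) stop("missing values not supported: unequal gene sets?")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  if (log) out <- log2(out + pseudocount)
  dimnames(out) <- dimnames(m)
  out
}
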