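# Fixed-width binned methylation tracks, with the coverage filter applied
# before any window arithmetic: bins whose summed CpG read coverage falls
# below the cutoff are treated as missing, exactly like bins with no CpG.

#' Low-level binned track constructor
#'
#' Mostly useful for building tracks directly in tests and simulations;
#' analysis code usually goes through [bin_methylation()].
#'
#' @param values Named list (one element per chromosome) of numeric bin
#'   values in \[0, 1\], `NA` = missing.
#' @param totals Named list of per-bin supporting totals (summed CpG read
#'   coverage); defaults to 1 for covered bins.
#' @param width Bin width in bp.
#' @param layout A [genome_layout()]; each chromosome must carry
#'   `ceiling(length / width)` bins.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, width, layout, totals = NULL) {
  stopifnot(width > 0, is.list(values))
  if (is.null(totals))
    totals <- lapply(values, function(v) as.numeric(!is.na(v)))
  unknown <- setdiff(names(values), names(layout))
  if (length(unknown))
    stop("chromosome(s) absent from genome layout: ",
         paste(unknown, collapse = ", "))
  for (chr in names(values)) {
    nb <- ceiling(unname(layout[chr]) / width)
    if (length(values[[chr]]) != nb)
      stop("chromosome ", chr, " needs ", nb, " bins of ", width,
           " bp, got ", length(values[[chr]]))
    v <- values[[chr]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("bin values must lie in [0, 1]")
    if (length(totals[[chr]]) != nb)
      stop("totals and values disagree in length on ", chr)
  }
  structure(list(width = width, layout = layout,
                 values = values, totals = totals),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  nb <- sum(lengths(x$values))
  nc <- sum(vapply(x$values, function(v) sum(!is.na(v)), numeric(1)))
  cat("binned_track: ", length(x$values), " chromosome(s), ",
      x$width, "-bp bins, ", nb, " bins (", nc, " covered)\n", sep = "")
  invisible(x)
}

#' Bin per-CpG methylation calls into a fixed-width track
#'
#' Bin methylation is coverage-weighted: (sum methylated) / (sum total) over
#' the CpGs in the bin ("methylated CpG versus total CpG"). Bins with summed
#' total coverage below `min_total_coverage`, or with no CpG at all, are
#' missing. Defaults give the 1-kb valley-calling track; `width = 200`
#' gives the QC track.
#'
#' @param calls A [methyl_calls()] object.
#' @param layout A [genome_layout()]; all call chromosomes must be present.
#' @param width Bin width in bp (default 1000).
#' @param min_total_coverage Minimum summed CpG read coverage per bin
#'   (default 5).
#' @param weighted If `FALSE`, use the unweighted mean of per-site
#'   methylation ratios instead (sensitivity analysis).
#' @return A [binned_track()]. The last bin of a chromosome may span fewer
#'   than `width` bp.
#' @export
bin_methylation <- function(calls, layout, width = 1000,
                            min_total_coverage = 5, weighted = TRUE) {
  stopifnot(inherits(calls, "methyl_calls"), width > 0,
            min_total_coverage >= 0)
  unknown <- setdiff(unique(calls$chrom), names(layout))
  if (length(unknown))
    stop("chromosome(s) absent from genome layout: ",
         paste(unknown, collapse = ", "))
  values <- totals <- stats::setNames(vector("list", length(layout)),
                                      names(layout))
  for (chr in names(layout)) {
    nb <- ceiling(unname(layout[chr]) / width)
    v <- rep(NA_real_, nb)
    tt <- numeric(nb)
    d <- calls[calls$chrom == chr, , drop = FALSE]
    if (nrow(d)) {
      if (any(d$pos >= unname(layout[chr])))
        stop("CpG position beyond chromosome ", chr)
      idx <- floor(d$pos / width) + 1
      msum <- rowsum(d$meth, idx)
      tsum <- rowsum(d$total, idx)
      at <- as.integer(rownames(msum))
      tt[at] <- tsum[, 1]
      if (weighted) {
        v[at] <- ifelse(tsum[, 1] > 0, msum[, 1] / tsum[, 1], NA_real_)
      } else {
        ratio <- ifelse(d$total > 0, d$meth / d$total, NA_real_)
        rsum <- rowsum(ratio, idx, na.rm = TRUE)
        rcnt <- rowsum(as.numeric(!is.na(ratio)), idx)
        v[at] <- ifelse(rcnt[, 1] > 0, rsum[, 1] / rcnt[, 1], NA_real_)
      }
      v[tt < min_total_coverage] <- NA_real_
    }
    values[[chr]] <- v
    totals[[chr]] <- tt
  }
  binned_track(values, width, layout, totals)
}

#' @export
as.data.frame.binned_track <- function(x, ...) {
  out <- lapply(names(x$values), function(chr) {
    v <- x$values[[chr]]
    n <- length(v)
    starts <- (seq_len(n) - 1) * x$width
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + x$width, unname(x$layout[chr])),
               value = v, total = x$totals[[chr]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export a binned track as bedGraph
#'
#' Missing bins are omitted.
#' @param x A [binned_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[!is.na(df$value), c("chrom", "start", "end", "value")]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# per-region (meth, total) count sums via cumulative sums on sorted calls
region_counts <- function(calls, regions) {
  n <- nrow(regions)
  meth <- total <- numeric(n)
  idx <- split(seq_len(n), regions$chrom)
  for (chr in names(idx)) {
    i <- idx[[chr]]
    d <- calls[calls$chrom == chr, , drop = FALSE]
    if (nrow(d) == 0) next
    cm <- c(0, cumsum(d$meth))
    ct <- c(0, cumsum(d$total))
    lo <- findInterval(regions$start[i] - 0.5, d$pos)      # sites with pos < start
    hi <- findInterval(regions$end[i] - 0.5, d$pos)        # sites with pos < end
    meth[i] <- cm[hi + 1] - cm[lo + 1]
    total[i] <- ct[hi + 1] - ct[lo + 1]
  }
  data.frame(meth = meth, total = total)
}

#' Mean methylation of genomic regions
#'
#' For per-CpG calls the mean is coverage-weighted
#' (sum methylated / sum total over CpGs inside the region). For a binned
#' track it is the mean over covered bins overlapping the region
#' (coverage-weighted across bins with `weighted = TRUE`). Regions with no
#' covered data give `NA`.
#'
#' @param x A [methyl_calls()] or [binned_track()] object.
#' @param regions An [interval_set()] (or data.frame with `chrom`, `start`,
#'   `end`).
#' @param ... Passed to methods.
#' @return Numeric vector, one mean per region.
#' @export
mean_methylation <- function(x, regions, ...) UseMethod("mean_methylation")

#' @export
mean_methylation.methyl_calls <- function(x, regions, ...) {
  rc <- region_counts(x, regions)
  ifelse(rc$total > 0, rc$meth / rc$total, NA_real_)
}

#' @rdname mean_methylation
#' @param weighted For the `binned_track` method: weight bins by their
#'   supporting totals.
#' @export
mean_methylation.binned_track <- function(x, regions, weighted = FALSE, ...) {
  n <- nrow(regions)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- x$values[[regions$chrom[i]]]
    if (is.null(v)) next
    b0 <- floor(regions$start[i] / x$width) + 1
    b1 <- ceiling(regions$end[i] / x$width)
    b1 <- min(b1, length(v))
    if (b1 < b0) next
    vv <- v[b0:b1]
    if (all(is.na(vv))) next
    if (weighted) {
      tt <- x$totals[[regions$chrom[i]]][b0:b1]
      out[i] <- sum(vv * tt, na.rm = TRUE) / sum(tt[!is.na(vv)])
    } else {
      out[i] <- mean(vv, na.rm = TRUE)
    }
  }
  out
}

#' CpG density of regions
#'
#' CpG sites per 100 bp: `100 * (#CpG sites inside) / region length`.
#' Site positions are taken from a [methyl_calls()] object or any data.frame
#' with `chrom` and `pos` columns, so no genome sequence is required.
#'
#' @param regions An [interval_set()].
#' @param sites CpG site positions ([methyl_calls()] or data.frame).
#' @return Numeric vector of densities, one per region.
#' @export
cg_density <- function(regions, sites) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  n <- nrow(regions)
  cnt <- numeric(n)
  idx <- split(seq_len(n), regions$chrom)
  for (chr in names(idx)) {
    i <- idx[[chr]]
    p <- sort(sites$pos[sites$chrom == chr])
    if (!length(p)) next
    cnt[i] <- findInterval(regions$end[i] - 0.5, p) -
      findInterval(regions$start[i] - 0.5, p)
  }
  100 * cnt / (regions$end - regions$start)
}
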