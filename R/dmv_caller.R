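# DMV calling: slide a 5-kb window in 1-kb steps over the 1-kb binned
# methylation track; windows whose mean over covered bins is < 0.15 qualify,
# and overlapping or book-ended qualifying windows are merged into maximal
# regions. Every call is therefore at least one window (5 kb) long.

#' Call DNA methylation valleys from a binned track
#'
#' A window qualifies when it holds at least `min_covered_bins` covered bins
#' and the mean methylation over its covered bins is strictly below
#' `max_meth`. Qualifying windows are merged (book-ended windows merge by
#' default); a merged region spans from the start of its first qualifying
#' window to the end of its last. Windows with too few covered bins are
#' skipped: they neither qualify nor break a valley. Chromosome tails
#' shorter than one window are never scanned.
#'
#' @param track A [binned_track()] whose width divides both `window` and
#'   `step` (the canonical inputs are 1-kb bins).
#' @param window Sliding window size in bp (default 5000).
#' @param step Window step in bp (default 1000).
#' @param max_meth Strict upper bound on window mean methylation
#'   (default 0.15).
#' @param min_covered_bins Minimum covered bins for a window to be assessed
#'   (default 3 of 5).
#' @param weighted Use a coverage-weighted window mean instead of the
#'   unweighted mean over covered bins (default `FALSE`, matching per-bin
#'   averaging).
#' @param merge_bookended Merge book-ended (end == next start) qualifying
#'   windows as well as overlapping ones (default `TRUE`).
#' @return An object of class `dmv_set`: a data.frame with columns `chrom`,
#'   `start`, `end`, `id`, `mean_meth` (coverage-weighted over the region's
#'   covered bins), `n_covered_bins`, plus the call parameters as
#'   attributes.
#' @seealso [dmv_summary()]
#' @export
call_dmvs <- function(track, window = 5000, step = 1000, max_meth = 0.15,
                      min_covered_bins = 3, weighted = FALSE,
                      merge_bookended = TRUE) {
  stopifnot(inherits(track, "binned_track"))
  w <- track$width
  if (window %% w != 0 || step %% w != 0)
    stop("bin width (", w, ") must divide window (", window,
         ") and step (", step, ")")
  wb <- window %/% w
  sb <- step %/% w
  out <- list()
  for (chr in names(track$values)) {
    len <- unname(track$layout[chr])
    if (len < window) next
    v <- track$values[[chr]]
    tt <- track$totals[[chr]]
    covered <- !is.na(v)
    v0 <- ifelse(covered, v, 0)
    t0 <- ifelse(covered, tt, 0)
    cv <- c(0, cumsum(v0))
    cc <- c(0, cumsum(covered))
    cvt <- c(0, cumsum(v0 * t0))
    ct <- c(0, cumsum(t0))
    # window start bins (0-based); tails shorter than one window not scanned
    starts <- seq(0, floor((len - window) / step)) * sb
    hi <- starts + wb
    nc <- cc[hi + 1] - cc[starts + 1]
    if (weighted) {
      tw <- ct[hi + 1] - ct[starts + 1]
      mu <- ifelse(tw > 0, (cvt[hi + 1] - cvt[starts + 1]) / tw, NA_real_)
    } else {
      mu <- ifelse(nc > 0, (cv[hi + 1] - cv[starts + 1]) / nc, NA_real_)
    }
    ok <- nc >= min_covered_bins & !is.na(mu) & mu < max_meth
    if (!any(ok)) next
    ws <- starts[ok] * w
    we <- ws + window
    # merge overlapping (and, by default, book-ended) qualifying windows
    keep_open <- if (merge_bookended) ws[-1] <= cumlag_max(we) else
      ws[-1] < cumlag_max(we)
    grp <- cumsum(c(TRUE, !keep_open))
    rs <- tapply(ws, grp, min)
    re <- tapply(we, grp, max)
    b0 <- rs / w + 1
    b1 <- re / w
    mm <- nb <- numeric(length(rs))
    for (k in seq_along(rs)) {
      i <- b0[k]:b1[k]
      cov_i <- covered[i]
      nb[k] <- sum(cov_i)
      tot <- sum(t0[i][cov_i])
      mm[k] <- if (tot > 0) sum((v0 * t0)[i][cov_i]) / tot else
        mean(v0[i][cov_i])
    }
    out[[chr]] <- data.frame(chrom = chr, start = as.numeric(rs),
                             end = as.numeric(re), mean_meth = mm,
                             n_covered_bins = nb, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mean_meth = numeric(), n_covered_bins = numeric())
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res$id <- if (nrow(res)) sprintf("DMV_%04d", seq_len(nrow(res))) else
    character(0)
  res <- res[, c("chrom", "start", "end", "id", "mean_meth",
                 "n_covered_bins")]
  structure(res, class = c("dmv_set", "interval_set", "data.frame"),
            params = list(window = window, step = step, max_meth = max_meth,
                          min_covered_bins = min_covered_bins,
                          weighted = weighted,
                          merge_bookended = merge_bookended,
                          bin_width = w))
}

# running maximum of the previous elements' ends, aligned with x[-1]
cumlag_max <- function(e) {
  if (length(e) <= 1) return(numeric(0))
  cummax(e)[-length(e)]
}

#' @export
print.dmv_set <- function(x, ...) {
  p <- attr(x, "params")
  cat("dmv_set: ", nrow(x), " valley(s)",
      if (!is.null(p)) paste0(" (window ", p$window, " bp, step ", p$step,
                              " bp, mean < ", p$max_meth, ")"), "\n",
      sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and ", nrow(x) - 10, " more\n", sep = "")
  invisible(x)
}

#' Summarize a set of called DMVs
#'
#' @param dmvs A [call_dmvs()] result (or any interval data.frame).
#' @return One-row data.frame: count, length quartiles (bp), total genome bp
#'   covered.
#' @export
dmv_summary <- function(dmvs) {
  if (nrow(dmvs) == 0)
    return(data.frame(n = 0L, min_len = NA_real_, q25_len = NA_real_,
                      median_len = NA_real_, q75_len = NA_real_,
                      max_len = NA_real_, total_bp = 0))
  len <- dmvs$end - dmvs$start
  q <- stats::quantile(len, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  data.frame(n = nrow(dmvs), min_len = q[1], q25_len = q[2],
             median_len = q[3], q75_len = q[4], max_len = q[5],
             total_bp = sum(len))
}

#' @export
summary.dmv_set <- function(object, ...) dmv_summary(object)

#' @export
plot.dmv_set <- function(x, ...) {
  if (nrow(x) == 0) {
    graphics::plot.new()
    graphics::title("dmv_set: no valleys")
    return(invisible(x))
  }
  graphics::hist((x$end - x$start) / 1e3, breaks = 20,
                 xlab = "DMV length (kb)", main = "DMV length distribution",
                 col = "grey80", ...)
  invisible(x)
}

#' Match called valleys against a truth set
#'
#' For each truth interval, finds the called interval with the largest
#' overlap and reports the interval Jaccard index (overlap bp / union bp)
#' and signed boundary errors. Called intervals matching no truth interval
#' (allowing `slop` bp) are counted as false calls.
#'
#' @param truth,called Interval data.frames (`chrom`, `start`, `end`).
#' @param slop Tolerance in bp when deciding whether a call lies outside
#'   truth (default 1000, one bin).
#' @return A list with `per_truth` (data.frame: jaccard, start_err, end_err
#'   per truth interval), `n_false` (calls not attributable to any truth
#'   interval) and `mean_jaccard`.
#' @export
valley_recovery <- function(truth, called, slop = 1000) {
  nt <- nrow(truth)
  res <- data.frame(jaccard = numeric(nt), start_err = rep(NA_real_, nt),
                    end_err = rep(NA_real_, nt))
  used <- rep(FALSE, nrow(called))
  for (i in seq_len(nt)) {
    j <- which(called$chrom == truth$chrom[i] &
                 called$start < truth$end[i] & called$end > truth$start[i])
    if (!length(j)) next
    ov <- pmin(called$end[j], truth$end[i]) -
      pmax(called$start[j], truth$start[i])
    best <- j[which.max(ov)]
    un <- max(called$end[best], truth$end[i]) -
      min(called$start[best], truth$start[i])
    res$jaccard[i] <- max(ov) / un
    res$start_err[i] <- called$start[best] - truth$start[i]
    res$end_err[i] <- called$end[best] - truth$end[i]
    used[j] <- TRUE
  }
  # a false call overlaps no truth interval even after expanding truth
  false_call <- rep(TRUE, nrow(called))
  for (i in seq_len(nt)) {
    hit <- called$chrom == truth$chrom[i] &
      called$start < truth$end[i] + slop &
      called$end > truth$start[i] - slop
    false_call[hit] <- FALSE
  }
  list(per_truth = res, n_false = sum(false_call),
       mean_jaccard = mean(res$jaccard))
}
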