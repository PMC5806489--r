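# Annotation of called valleys: chromatin state from histone-mark peaks,
# CGI / non-CGI partition, knockout-vs-wild-type methylation change,
# TF-site density meta-profiles with length-matched random controls, and
# score comparisons stratified by CpG density.

.any_overlap <- function(a, b) {
  out <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    out[i] <- any(b$chrom == a$chrom[i] & b$start < a$end[i] &
                    b$end > a$start[i])
  }
  out
}

#' Chromatin state of valleys from histone-mark peaks
#'
#' State is decided by any-overlap (>= 1 bp) with H3K4me3 and H3K27me3 peak
#' sets; the four states (K4-only, K27-only, K4+K27, none) are mutually
#' exclusive and exhaustive. A valley overlapping a Polycomb-component peak
#' set (e.g. EED) is flagged as a Polycomb valley.
#'
#' @param dmvs Valley data.frame with `id`.
#' @param k4_peaks,k27_peaks [interval_set()] of H3K4me3 / H3K27me3 peaks.
#' @param polycomb_peaks Optional [interval_set()] (e.g. EED ChIP peaks).
#' @return data.frame (`id`, `state`, `polycomb`).
#' @export
chromatin_state <- function(dmvs, k4_peaks, k27_peaks,
                            polycomb_peaks = NULL) {
  k4 <- .any_overlap(dmvs, k4_peaks)
  k27 <- .any_overlap(dmvs, k27_peaks)
  state <- ifelse(k4 & k27, "K4+K27",
                  ifelse(k4, "K4-only", ifelse(k27, "K27-only", "none")))
  pc <- if (is.null(polycomb_peaks)) rep(FALSE, nrow(dmvs)) else
    .any_overlap(dmvs, polycomb_peaks)
  data.frame(id = dmvs$id,
             state = factor(state, levels = c("K4-only", "K27-only",
                                              "K4+K27", "none")),
             polycomb = pc, stringsAsFactors = FALSE)
}

#' Partition valleys into CGI and non-CGI parts
#'
#' The CGI parts are the intersection with the CGI set, the non-CGI parts
#' the remainder; together they tile each valley exactly.
#'
#' @param dmvs Valley data.frame with `id`.
#' @param cgis CGI [interval_set()].
#' @return List with `cgi` and `non_cgi` interval sets; the `name` column
#'   holds the originating valley id.
#' @export
partition_cgi <- function(dmvs, cgis) {
  x <- interval_set(data.frame(chrom = dmvs$chrom, start = dmvs$start,
                               end = dmvs$end, name = dmvs$id,
                               stringsAsFactors = FALSE))
  list(cgi = interval_intersect(x, cgis),
       non_cgi = interval_subtract(x, cgis))
}

#' Methylation change between paired methylomes
#'
#' Computes coverage-weighted mean methylation per region in each methylome
#' and the change `delta_m = m_ko - m_wt`; a region is hypermethylated when
#' `delta_m >= hyper_threshold`. When a CGI set is supplied, the change is
#' additionally computed on the CGI and non-CGI parts of each region.
#' Regions without coverage in either methylome give `NA` (a warning
#' reports how many).
#'
#' @param wt_calls,ko_calls [methyl_calls()] on the same genome layout.
#' @param regions Valley data.frame with `id`.
#' @param cgis Optional CGI [interval_set()].
#' @param hyper_threshold Minimum `delta_m` to flag hypermethylation
#'   (default 0.1).
#' @return data.frame per region: `m_wt`, `m_ko`, `delta_m`, `hyper`, and
#'   (with CGIs) `delta_cgi`, `delta_non_cgi`.
#' @export
methylation_change <- function(wt_calls, ko_calls, regions, cgis = NULL,
                               hyper_threshold = 0.1) {
  m_wt <- mean_methylation(wt_calls, regions)
  m_ko <- mean_methylation(ko_calls, regions)
  out <- data.frame(id = regions$id, m_wt = m_wt, m_ko = m_ko,
                    delta_m = m_ko - m_wt, stringsAsFactors = FALSE)
  out$hyper <- !is.na(out$delta_m) & out$delta_m >= hyper_threshold
  if (!is.null(cgis)) {
    parts <- partition_cgi(regions, cgis)
    out$delta_cgi <- .part_delta(wt_calls, ko_calls, parts$cgi, regions$id)
    out$delta_non_cgi <- .part_delta(wt_calls, ko_calls, parts$non_cgi,
                                     regions$id)
    # hypermethylation is assessed separately on the CGI and non-CGI parts:
    # CpG-dense islands dominate the count-weighted whole-region mean, so a
    # purely non-CGI methylation gain is diluted in `delta_m`
    out$hyper_cgi <- !is.na(out$delta_cgi) & out$delta_cgi >= hyper_threshold
    out$hyper_non_cgi <- !is.na(out$delta_non_cgi) &
      out$delta_non_cgi >= hyper_threshold
  }
  n_na <- sum(is.na(out$delta_m))
  if (n_na)
    warning(n_na, " region(s) without coverage in one methylome: delta_m = NA")
  out
}

# pooled (count-weighted) delta over the parts belonging to each region id
.part_delta <- function(wt, ko, parts, ids) {
  out <- rep(NA_real_, length(ids))
  if (nrow(parts) == 0) return(out)
  cw <- region_counts(wt, parts)
  ck <- region_counts(ko, parts)
  mw <- rowsum(cw$meth, parts$name)
  tw <- rowsum(cw$total, parts$name)
  mk <- rowsum(ck$meth, parts$name)
  tk <- rowsum(ck$total, parts$name)
  at <- match(ids, rownames(mw))
  ok <- !is.na(at)
  okk <- ok & tw[at[ok], 1] > 0 & tk[at[ok], 1] > 0
  okk[is.na(okk)] <- FALSE
  i <- at[okk]
  out[okk] <- mk[i, 1] / tk[i, 1] - mw[i, 1] / tw[i, 1]
  out
}

#' Meta-profile of site density around regions
#'
#' Each region body is rescaled to `body_bins` equal bins; fixed-width
#' flanks of `flank_bp` on each side are cut into `flank_bins` bins. Site
#' interval midpoints are counted per bin and converted to sites per kb;
#' the profile is the mean over regions.
#'
#' @param sites [interval_set()] of sites (e.g. TF binding sites).
#' @param regions Non-empty valley data.frame.
#' @param flank_bp Flank size in bp on each side (default 20000).
#' @param body_bins Number of scaled bins across the region body
#'   (default 20).
#' @param flank_bins Number of fixed-width bins per flank (default 20).
#' @return data.frame of class `meta_profile` with columns `bin`, `zone`
#'   (upstream/body/downstream) and `density` (sites per kb).
#' @export
site_density_profile <- function(sites, regions, flank_bp = 20000,
                                 body_bins = 20, flank_bins = 20) {
  stopifnot(nrow(regions) > 0, body_bins > 0, flank_bins > 0, flank_bp > 0)
  nb <- 2 * flank_bins + body_bins
  acc <- matrix(0, nrow(regions), nb)
  mids <- interval_midpoints(sites)
  for (i in seq_len(nrow(regions))) {
    p <- sort(mids[sites$chrom == regions$chrom[i]])
    s <- regions$start[i]
    e <- regions$end[i]
    edges <- c(seq(s - flank_bp, s, length.out = flank_bins + 1),
               seq(s, e, length.out = body_bins + 1)[-1],
               seq(e, e + flank_bp, length.out = flank_bins + 1)[-1])
    counts <- if (length(p)) diff(findInterval(edges - 0.5, p)) else
      numeric(nb)
    widths <- diff(edges)
    acc[i, ] <- counts / (widths / 1000)
  }
  zone <- rep(c("upstream", "body", "downstream"),
              c(flank_bins, body_bins, flank_bins))
  out <- data.frame(bin = seq_len(nb), zone = zone,
                    density = colMeans(acc))
  class(out) <- c("meta_profile", "data.frame")
  attr(out, "flank_bp") <- flank_bp
  attr(out, "n_regions") <- nrow(regions)
  out
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$bin, x$density, type = "l",
                 xlab = "bin (flank | scaled body | flank)",
                 ylab = "sites per kb", ...)
  at <- range(which(x$zone == "body"))
  graphics::abline(v = at + c(-0.5, 0.5), lty = 2, col = "grey50")
  invisible(x)
}

#' Length-matched random control regions
#'
#' For each of `n_draws` draws, every region's length is placed uniformly
#' at random on the genome (chromosome chosen proportional to its length
#' among chromosomes long enough), avoiding `exclude` by rejection
#' sampling. Fully reproducible under `seed`.
#'
#' @param regions Region data.frame (`chrom`, `start`, `end`, optional
#'   `id`).
#' @param layout A [genome_layout()].
#' @param n_draws Number of control draws (default 1).
#' @param seed Optional integer seed.
#' @param exclude Optional [interval_set()] placements must not overlap.
#' @param max_tries Rejection-sampling cap per placement (default 1000).
#' @return [interval_set()] of controls with columns `name` (source region
#'   id) and `draw`.
#' @export
random_length_matched_controls <- function(regions, layout, n_draws = 1,
                                           seed = NULL, exclude = NULL,
                                           max_tries = 1000) {
  lens <- rep(regions$end - regions$start, times = n_draws)
  draw <- rep(seq_len(n_draws), each = nrow(regions))
  ids <- rep(if (!is.null(regions$id)) regions$id else
    as.character(seq_len(nrow(regions))), times = n_draws)
  if (any(lens > max(layout)))
    stop("region longer than every chromosome: ",
         ids[which.max(lens)])
  ex <- if (!is.null(exclude) && nrow(exclude)) interval_union(exclude) else
    NULL
  with_seed(seed, {
    n <- length(lens)
    chrom <- character(n)
    start <- numeric(n)
    todo <- seq_len(n)
    tries <- 0L
    cl <- as.numeric(layout)
    cn <- names(layout)
    while (length(todo)) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place region ", ids[todo[1]],
             " after ", max_tries, " tries (exclusion too dense?)")
      for (j in todo) {
        okc <- which(cl >= lens[j])
        ci <- okc[sample.int(length(okc), 1, prob = cl[okc])]
        chrom[j] <- cn[ci]
        start[j] <- floor(stats::runif(1, 0, cl[ci] - lens[j] + 1))
      }
      if (is.null(ex)) break
      bad <- vapply(todo, function(j) {
        any(ex$chrom == chrom[j] & ex$start < start[j] + lens[j] &
              ex$end > start[j])
      }, logical(1))
      todo <- todo[bad]
    }
    out <- data.frame(chrom = chrom, start = start, end = start + lens,
                      name = ids, stringsAsFactors = FALSE)
    out$draw <- draw
    out <- interval_set(out)
    out
  })
}

#' Site density of a region set
#'
#' Total site midpoints falling inside the regions divided by the total
#' region length in kb.
#'
#' @param sites [interval_set()] of sites.
#' @param regions Region data.frame.
#' @return Sites per kb (scalar).
#' @export
region_site_density <- function(sites, regions) {
  mids <- interval_midpoints(sites)
  cnt <- 0
  for (chr in unique(regions$chrom)) {
    p <- sort(mids[sites$chrom == chr])
    if (!length(p)) next
    r <- regions[regions$chrom == chr, , drop = FALSE]
    cnt <- cnt + sum(findInterval(r$end - 0.5, p) -
                       findInterval(r$start - 0.5, p))
  }
  cnt / (sum(regions$end - regions$start) / 1000)
}

#' Empirical enrichment test against control densities
#'
#' One-sided empirical p-value with add-one smoothing,
#' `p = (1 + #{controls >= observed}) / (1 + n)`, and the fold change
#' `observed / mean(controls)`. Never anti-conservative: p is bounded below
#' by `1 / (1 + n)`.
#'
#' @param observed_density Observed site density (scalar).
#' @param control_densities Numeric vector of control densities
#'   (>= 100 draws recommended).
#' @return List of class `enrichment_test`: `p`, `fold` (`NA` with
#'   `fold_defined = FALSE` when the control mean is 0), `n_controls`,
#'   `observed`, `control_mean`.
#' @export
enrichment_test <- function(observed_density, control_densities) {
  n <- length(control_densities)
  if (n < 100)
    warning("fewer than 100 control draws (", n, "); p is coarse")
  p <- (1 + sum(control_densities >= observed_density)) / (1 + n)
  cm <- mean(control_densities)
  fold <- if (cm == 0) NA_real_ else observed_density / cm
  structure(list(p = p, fold = fold, fold_defined = cm > 0,
                 n_controls = n, observed = observed_density,
                 control_mean = cm),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat("enrichment test: observed ", signif(x$observed, 4), "/kb vs ",
      x$n_controls, " controls (mean ", signif(x$control_mean, 4),
      "/kb)\n  fold = ", signif(x$fold, 4), ", empirical p = ",
      signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Site enrichment in regions vs length-matched random controls
#'
#' Convenience wrapper: computes the observed site density over `regions`,
#' draws `n_draws` length-matched control sets, and runs
#' [enrichment_test()].
#'
#' @inheritParams random_length_matched_controls
#' @param sites [interval_set()] of sites.
#' @return An [enrichment_test()] result with the per-draw
#'   `control_densities` attached.
#' @export
tf_site_enrichment <- function(sites, regions, layout, n_draws = 1000,
                               seed = NULL, exclude = NULL) {
  obs <- region_site_density(sites, regions)
  ctrl <- random_length_matched_controls(regions, layout, n_draws, seed,
                                         exclude)
  dens <- vapply(split(ctrl, ctrl$draw), function(d)
    region_site_density(sites, d), numeric(1))
  res <- enrichment_test(obs, unname(dens))
  res$control_densities <- unname(dens)
  res
}

#' Score comparison stratified by CpG density
#'
#' Pools the CpG densities of both sets, cuts them into `n_strata` quantile
#' strata, and summarizes the score distribution of each set within each
#' stratum (e.g. deamination-rate-like scores of CGIs inside vs outside
#' valleys).
#'
#' @param a,b data.frames with numeric columns `cg_density` and `score`.
#' @param n_strata Number of quantile strata (default 4).
#' @return data.frame with one row per stratum x set: `stratum`, `set`,
#'   `n`, `median`, `q25`, `q75`. Quantile breaks are attached as an
#'   attribute.
#' @export
stratified_score_compare <- function(a, b, n_strata = 4) {
  stopifnot(all(c("cg_density", "score") %in% names(a)),
            all(c("cg_density", "score") %in% names(b)))
  pool <- c(a$cg_density, b$cg_density)
  breaks <- unique(stats::quantile(pool, probs = seq(0, 1,
                                                     length.out = n_strata + 1)))
  cut_strat <- function(x) cut(x, breaks, include.lowest = TRUE,
                               labels = FALSE)
  summarize <- function(d, setname) {
    s <- cut_strat(d$cg_density)
    do.call(rbind, lapply(seq_len(length(breaks) - 1), function(k) {
      sc <- d$score[!is.na(s) & s == k]
      data.frame(stratum = k, set = setname, n = length(sc),
                 median = if (length(sc)) stats::median(sc) else NA_real_,
                 q25 = if (length(sc)) unname(stats::quantile(sc, 0.25)) else NA_real_,
                 q75 = if (length(sc)) unname(stats::quantile(sc, 0.75)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(summarize(a, "a"), summarize(b, "b"))
  out <- out[order(out$stratum, out$set), ]
  rownames(out) <- NULL
  attr(out, "breaks") <- breaks
  out
}

#' Percentage of valleys per group overlapping a feature set
#'
#' @param dmvs Valley data.frame.
#' @param features [interval_set()] (e.g. super-enhancers).
#' @param groups Vector of group labels aligned with `dmvs` rows.
#' @return data.frame per group: `group`, `n`, `n_overlap`, `pct`
#'   (100 * overlap count / group size; `NaN` for empty groups).
#' @export
overlap_percentage <- function(dmvs, features, groups) {
  stopifnot(length(groups) == nrow(dmvs))
  hit <- .any_overlap(dmvs, features)
  lv <- if (is.factor(groups)) levels(groups) else unique(groups)
  do.call(rbind, lapply(lv, function(g) {
    sel <- groups == g
    data.frame(group = g, n = sum(sel), n_overlap = sum(hit & sel),
               pct = 100 * sum(hit & sel) / sum(sel),
               stringsAsFactors = FALSE)
  }))
}
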