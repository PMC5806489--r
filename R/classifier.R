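# Group I/II/III classification. A valley is "dynamic" when tissue-specific
# differentially methylated regions (tsDMRs, > 2 kb) either sit entirely
# inside it or cover more than half of it. Dynamic valleys whose associated
# dynamically expressed gene shows a negative methylation-expression
# correlation across the four lineages are group II; a positive correlation
# gives group III; everything non-dynamic is group I (constant).

#' Decide whether valleys are dynamic from tsDMR overlap
#'
#' A DMV is dynamic iff it contains at least one entire tsDMR, or more than
#' `min_cover` of its bp is covered by tsDMRs. Only tsDMRs strictly longer
#' than `min_tsdmr_len` are used; the filter is applied here, so the input
#' need not be pre-filtered.
#'
#' @param dmvs Interval data.frame of valleys (with `id` column if
#'   available).
#' @param tsdmrs [interval_set()] of tsDMRs.
#' @param min_tsdmr_len Strict minimum tsDMR length in bp (default 2000).
#' @param min_cover Strict coverage-fraction threshold (default 0.5).
#' @return data.frame with one row per DMV: `dynamic`, `n_contained`
#'   (tsDMRs fully inside), `tsdmr_cover` (covered fraction).
#' @export
is_dynamic_dmv <- function(dmvs, tsdmrs, min_tsdmr_len = 2000,
                           min_cover = 0.5) {
  ts <- filter_by_length(tsdmrs, min_tsdmr_len)
  n <- nrow(dmvs)
  contained <- integer(n)
  for (i in seq_len(n)) {
    contained[i] <- sum(ts$chrom == dmvs$chrom[i] &
                          ts$start >= dmvs$start[i] & ts$end <= dmvs$end[i])
  }
  cover <- if (nrow(ts)) coverage_fraction(dmvs, ts) else numeric(n)
  data.frame(id = if (!is.null(dmvs$id)) dmvs$id else as.character(seq_len(n)),
             dynamic = contained > 0 | cover > min_cover,
             n_contained = contained, tsdmr_cover = cover,
             stringsAsFactors = FALSE)
}

#' Dynamic-gene rule on per-lineage expression
#'
#' A gene is dynamically expressed when its highest per-lineage FPKM is at
#' least `min_peak`, the mean FPKM of the remaining lineages is at most
#' `max_rest_mean`, and the peak is at least `fold` times that mean.
#'
#' @param fpkm_by_lineage Numeric vector of one mean FPKM per lineage.
#' @param min_peak Minimum peak FPKM (default 2).
#' @param fold Minimum peak / rest-mean ratio (default 3).
#' @param max_rest_mean Maximum mean FPKM of the non-peak lineages
#'   (default 2).
#' @return Logical flag.
#' @export
is_dynamic_gene <- function(fpkm_by_lineage, min_peak = 2, fold = 3,
                            max_rest_mean = 2) {
  f <- as.numeric(fpkm_by_lineage)
  if (length(f) < 2 || anyNA(f))
    stop("need one non-missing FPKM per lineage (>= 2 lineages), got ",
         length(f))
  peak <- which.max(f)
  rest <- mean(f[-peak])
  f[peak] >= min_peak && rest <= max_rest_mean && f[peak] >= fold * rest
}

#' Associate genes with valleys by TSS position
#'
#' A gene is associated with a DMV when its TSS lies inside the DMV extended
#' by `max_dist` bp on each side (half-open: a TSS exactly at the extended
#' end coordinate is outside).
#'
#' @param dmvs Interval data.frame of valleys with `id` column.
#' @param tss [interval_set()] of TSS records (1-bp intervals; `name` is the
#'   gene id; position is `start`).
#' @param max_dist Extension in bp (default 0).
#' @return data.frame (`id`, `gene`, `tss_pos`, `distance`), ordered by
#'   DMV, then distance to the valley, then gene id.
#' @export
associate_genes <- function(dmvs, tss, max_dist = 0) {
  stopifnot(!is.null(tss$name))
  rows <- list()
  for (i in seq_len(nrow(dmvs))) {
    sel <- tss$chrom == dmvs$chrom[i] &
      tss$start >= dmvs$start[i] - max_dist &
      tss$start < dmvs$end[i] + max_dist
    if (!any(sel)) next
    p <- tss$start[sel]
    dist <- pmax(0, pmax(dmvs$start[i] - p, p - (dmvs$end[i] - 1)))
    d <- data.frame(id = dmvs$id[i], gene = tss$name[sel], tss_pos = p,
                    distance = dist, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- d[order(d$distance, d$gene), , drop = FALSE]
  }
  if (!length(rows))
    return(data.frame(id = character(), gene = character(),
                      tss_pos = numeric(), distance = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Methylation-expression correlation across lineages
#'
#' Pearson correlation between per-lineage mean methylation and per-lineage
#' mean FPKM. With only four lineages the magnitude is weakly determined;
#' only the sign is used for grouping, and no significance test is
#' attempted. Returns `NA` when either vector is constant (correlation
#' undefined).
#'
#' @param meth_by_lineage,fpkm_by_lineage Equal-length numeric vectors
#'   (n >= 3).
#' @return Pearson r in \[-1, 1\], or `NA` if undefined.
#' @export
meth_expr_correlation <- function(meth_by_lineage, fpkm_by_lineage) {
  m <- as.numeric(meth_by_lineage)
  e <- as.numeric(fpkm_by_lineage)
  if (length(m) != length(e))
    stop("methylation and expression vectors differ in length")
  if (length(m) < 3)
    stop("need at least 3 lineages for a correlation, got ", length(m))
  if (stats::sd(m) == 0 || stats::sd(e) == 0) return(NA_real_)
  stats::cor(m, e)
}

#' Classify valleys into groups I, II and III
#'
#' Non-dynamic DMVs are constant (group I). Dynamic DMVs are assigned by
#' the sign of the methylation-expression correlation of their associated
#' dynamically expressed gene: negative gives group II, positive group III.
#' Dynamic DMVs without a dynamic gene, with conflicting candidates (|r|
#' tie between genes), or with an undefined/zero correlation are reported
#' as `dynamic-unassigned` rather than forced into II/III. When several
#' associated genes are dynamic, the gene with the largest |r| is used.
#'
#' @param dmvs Valley data.frame with `id`.
#' @param tsdmrs tsDMR [interval_set()].
#' @param meth_by_lineage Numeric DMV x lineage matrix of mean methylation;
#'   rownames must be DMV ids, colnames the lineage labels.
#' @param expr An [expression_matrix()].
#' @param gene_map data.frame (`id`, `gene`) mapping DMVs to candidate
#'   genes, e.g. from [associate_genes()].
#' @param min_tsdmr_len,min_cover Passed to [is_dynamic_dmv()].
#' @param min_peak,fold,max_rest_mean Passed to [is_dynamic_gene()].
#' @return data.frame of class `dmv_classification`: per DMV the `label`
#'   (factor I / II / III / dynamic-unassigned) and evidence columns
#'   (`dynamic`, `tsdmr_cover`, `n_contained`, `gene`, `r`).
#' @export
classify_dmvs <- function(dmvs, tsdmrs, meth_by_lineage, expr, gene_map,
                          min_tsdmr_len = 2000, min_cover = 0.5,
                          min_peak = 2, fold = 3, max_rest_mean = 2) {
  if (nrow(dmvs) == 0) {
    out <- data.frame(id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      label = factor(character(),
                                     levels = c("I", "II", "III",
                                                "dynamic-unassigned")),
                      dynamic = logical(), n_contained = integer(),
                      tsdmr_cover = numeric(), gene = character(),
                      r = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("dmv_classification", "data.frame")
    return(out)
  }
  lineages <- colnames(meth_by_lineage)
  if (is.null(lineages) || is.null(rownames(meth_by_lineage)))
    stop("'meth_by_lineage' needs DMV-id rownames and lineage colnames")
  missing <- setdiff(dmvs$id, rownames(meth_by_lineage))
  if (length(missing))
    stop("missing lineage methylation for DMV(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  bad <- dmvs$id[apply(is.na(meth_by_lineage[dmvs$id, , drop = FALSE]), 1, any)]
  if (length(bad))
    stop("NA lineage methylation for DMV(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  em <- lineage_means(expr)
  miss_lin <- setdiff(lineages, colnames(em))
  if (length(miss_lin))
    stop("expression matrix lacks lineage(s): ",
         paste(miss_lin, collapse = ", "))
  em <- em[, lineages, drop = FALSE]

  dyn <- is_dynamic_dmv(dmvs, tsdmrs, min_tsdmr_len, min_cover)
  n <- nrow(dmvs)
  label <- character(n)
  gene <- rep(NA_character_, n)
  rr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!dyn$dynamic[i]) {
      label[i] <- "I"
      next
    }
    cand <- gene_map$gene[gene_map$id == dmvs$id[i]]
    cand <- intersect(cand, rownames(em))
    cand <- cand[vapply(cand, function(g)
      is_dynamic_gene(em[g, ], min_peak, fold, max_rest_mean), logical(1))]
    if (!length(cand)) {
      label[i] <- "dynamic-unassigned"
      next
    }
    mvec <- meth_by_lineage[dmvs$id[i], ]
    r <- vapply(cand, function(g) meth_expr_correlation(mvec, em[g, ]),
                numeric(1))
    ok <- !is.na(r)
    if (!any(ok)) {
      label[i] <- "dynamic-unassigned"
      next
    }
    r <- r[ok]
    cand <- cand[ok]
    best <- which(abs(r) > max(abs(r)) - 1e-12)
    if (length(best) > 1 && length(unique(sign(r[best]))) > 1) {
      label[i] <- "dynamic-unassigned"   # conflicting ties
      next
    }
    best <- best[1]
    gene[i] <- cand[best]
    rr[i] <- r[best]
    label[i] <- if (r[best] < 0) "II" else if (r[best] > 0) "III" else
      "dynamic-unassigned"
  }
  out <- data.frame(id = dmvs$id, chrom = dmvs$chrom, start = dmvs$start,
                    end = dmvs$end,
                    label = factor(label, levels = c("I", "II", "III",
                                                     "dynamic-unassigned")),
                    dynamic = dyn$dynamic, n_contained = dyn$n_contained,
                    tsdmr_cover = dyn$tsdmr_cover, gene = gene, r = rr,
                    stringsAsFactors = FALSE)
  class(out) <- c("dmv_classification", "data.frame")
  out
}

#' @export
print.dmv_classification <- function(x, ...) {
  cat("dmv_classification:", nrow(x), "valleys\n")
  print(table(x$label))
  invisible(x)
}

#' Per-valley, per-lineage mean methylation from raw calls
#'
#' Convenience builder for the classifier input: coverage-weighted mean
#' methylation of every valley in every lineage methylome.
#'
#' @param dmvs Valley data.frame with `id`.
#' @param calls_by_lineage Named list of [methyl_calls()], one per lineage.
#' @return DMV x lineage numeric matrix with DMV-id rownames.
#' @export
dmv_lineage_methylation <- function(dmvs, calls_by_lineage) {
  m <- sapply(calls_by_lineage, function(cl) mean_methylation(cl, dmvs))
  m <- matrix(m, nrow = nrow(dmvs),
              dimnames = list(dmvs$id, names(calls_by_lineage)))
  m
}
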