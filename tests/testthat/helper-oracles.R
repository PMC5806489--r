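# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately use per-bp boolean masks and naive
# enumeration so they share no code with the implementations they check.

# boolean occupancy mask of an interval set on one chromosome of `len` bp
mask_of <- function(df, len, chrom = "chr1") {
  m <- rep(FALSE, len)
  d <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) m[(d$start[i] + 1):d$end[i]] <- TRUE
  m
}

# runs of TRUE in a mask -> interval data.frame (0-based half-open)
mask_to_intervals <- function(m, chrom = "chr1") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(chrom = rep(chrom, sum(r$values)),
             start = starts[r$values], end = ends[r$values])
}

# per-record mask subtraction/intersection oracle
oracle_clip <- function(a, b, len, keep) {
  bm <- mask_of(b, len)
  out <- list()
  for (i in seq_len(nrow(a))) {
    seg <- bm[(a$start[i] + 1):a$end[i]]
    if (keep == "outside") seg <- !seg
    if (!any(seg)) next
    iv <- mask_to_intervals(seg, a$chrom[i])
    iv$start <- iv$start + a$start[i]
    iv$end <- iv$end + a$start[i]
    out[[length(out) + 1]] <- iv
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  do.call(rbind, out)
}

oracle_coverage <- function(a, b, len) {
  bm <- mask_of(b, len)
  vapply(seq_len(nrow(a)), function(i)
    mean(bm[(a$start[i] + 1):a$end[i]]), numeric(1))
}

# exhaustive window enumeration + per-bp mask merge; the reference for the
# valley caller (book-ended merging is implicit in the bp mask)
oracle_call_dmvs <- function(values, width, len, window = 5000,
                             step = 1000, max_meth = 0.15, min_cov = 3) {
  m <- rep(FALSE, len)
  if (len >= window) {
    for (s in seq(0, len - window, by = step)) {
      b <- values[(s / width + 1):((s + window) / width)]
      nc <- sum(!is.na(b))
      if (nc >= min_cov && mean(b, na.rm = TRUE) < max_meth)
        m[(s + 1):(s + window)] <- TRUE
    }
  }
  mask_to_intervals(m)
}

# random binned track exercising low valleys, near-threshold stretches and
# missing bins
random_track <- function(seed, n_bins = 1000, width = 1000) {
  set.seed(seed)
  v <- runif(n_bins, 0.4, 1)
  for (k in seq_len(sample(0:4, 1))) {
    w <- sample(4:15, 1)
    s <- sample(n_bins - w, 1)
    v[s:(s + w)] <- runif(w + 1, 0, 0.12)
  }
  for (k in seq_len(sample(0:3, 1))) {
    w <- sample(3:8, 1)
    s <- sample(n_bins - w, 1)
    v[s:(s + w)] <- runif(w + 1, 0.10, 0.20)
  }
  v[runif(n_bins) < 0.05] <- NA
  layout <- genome_layout(c(chr1 = n_bins * width))
  binned_track(list(chr1 = v), width, layout)
}

# random disjoint interval set on one chromosome
random_disjoint_set <- function(n, len, named = TRUE) {
  edges <- sort(sample(0:len, 2 * n))
  df <- data.frame(chrom = "chr1", start = edges[seq(1, 2 * n, 2)],
                   end = edges[seq(2, 2 * n, 2)])
  df <- df[df$start < df$end, , drop = FALSE]
  if (named) df$name <- sprintf("iv%03d", seq_len(nrow(df)))
  interval_set(df)
}

# small simulation config for fast unit tests
tiny_config <- function(seed = 5, ...) {
  dmv_sim_config(seed = seed, n_chrom = 1, chrom_length = 1e6,
                 n_valleys = 6, n_background_cgis = 8,
                 n_decoy_tsdmrs = 4, n_background_genes = 5,
                 coverage = 20, ...)
}
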