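# Seeded synthetic study generator. Emulates the statistical structure the
# valley analysis assumes: a CpG landscape with dense unmethylated islands,
# a highly methylated background, planted hypomethylated valleys >= 5 kb
# with constant (I) and dynamic (II/III) lineage behaviour, tsDMRs inside
# dynamic valleys, binomial bisulfite sampling at Poisson coverage, and a
# WT/KO methylome pair whose hypermethylation is confined to the non-CGI
# parts of Polycomb-like valleys. Every output is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' Defaults describe the canonical validation study: a 10-Mb two-chromosome
#' genome, 50 grid-aligned valleys of 5-40 kb at 70/20/10 group
#' proportions, Beta(8, 2) background methylation (mean 0.8), Poisson
#' coverage lambda = 30 per lineage, and a KO methylation gain of 0.3 on
#' non-CGI valley parts.
#'
#' @param seed Integer master seed; component sub-seeds are derived from it.
#' @param n_chrom,chrom_length Genome shape (bp per chromosome).
#' @param cpg_spacing Mean background CpG spacing in bp (geometric gaps).
#' @param cgi_spacing Mean CpG spacing inside CpG islands (bp).
#' @param cgi_length CGI length range in bp.
#' @param cgis_per_valley CGIs planted inside each valley.
#' @param n_background_cgis CGIs planted outside valleys.
#' @param n_valleys Number of planted valleys.
#' @param valley_length Valley length range in bp (snapped to the 1-kb
#'   grid).
#' @param group_props Named proportions for groups I, II, III (sum to 1).
#' @param valley_meth True methylation of constant-valley CpGs.
#' @param dynamic_meth_levels Per-lineage true methylation levels assigned
#'   (in random order) to each dynamic valley; all < 0.15 so dynamic
#'   valleys stay callable in every lineage.
#' @param cgi_meth True methylation of CGI CpGs (constitutively low).
#' @param background_beta `c(alpha, beta)` of the background Beta
#'   methylation distribution.
#' @param coverage Poisson mean read coverage per CpG and lineage.
#' @param lineages Lineage labels (default the four germ-layer groupings).
#' @param samples_per_lineage Expression samples per lineage.
#' @param peak_fpkm,basal_fpkm FPKM ranges for dynamic-gene peak and basal
#'   lineages.
#' @param expr_noise_sd Log-normal noise SD on sample-level FPKM.
#' @param tsdmr_length Planted tsDMR length range in bp (> 2 kb).
#' @param n_decoy_tsdmrs Background tsDMRs away from valleys (half of them
#'   shorter than 2 kb, exercising the length filter).
#' @param n_background_genes Flat-expressed genes outside valleys.
#' @param ko_delta KO - WT methylation gain on non-CGI parts of Polycomb
#'   valleys, in `[0, 1 - valley_meth]`.
#' @param tf_rate Background TF-site density (sites per kb).
#' @param tf_fold TF-site enrichment fold inside valleys (>= 1).
#' @param se_frac Named per-group probabilities that a valley carries a
#'   super-enhancer.
#' @param min_gap Minimum gap between planted valleys (bp).
#' @return A list of class `dmv_sim_config`.
#' @export
dmv_sim_config <- function(seed = 1,
                           n_chrom = 2, chrom_length = 5e6,
                           cpg_spacing = 100, cgi_spacing = 10,
                           cgi_length = c(500, 2000),
                           cgis_per_valley = 2, n_background_cgis = 40,
                           n_valleys = 50, valley_length = c(5000, 40000),
                           group_props = c(I = 0.7, II = 0.2, III = 0.1),
                           valley_meth = 0.03,
                           dynamic_meth_levels = c(0.02, 0.05, 0.08, 0.11),
                           cgi_meth = 0.02,
                           background_beta = c(8, 2),
                           coverage = 30,
                           lineages = c("blood", "endoderm", "mesoderm",
                                        "ectoderm"),
                           samples_per_lineage = 2,
                           peak_fpkm = c(6, 20), basal_fpkm = c(0, 1.2),
                           expr_noise_sd = 0.05,
                           tsdmr_length = c(2500, 4000),
                           n_decoy_tsdmrs = 10,
                           n_background_genes = 30,
                           ko_delta = 0.3,
                           tf_rate = 0.5, tf_fold = 3,
                           se_frac = c(I = 0.05, II = 0.3, III = 0.15),
                           min_gap = 10000) {
  cfg <- as.list(environment())
  if (abs(sum(group_props) - 1) > 1e-8)
    stop("group proportions must sum to 1")
  if (!setequal(names(group_props), c("I", "II", "III")))
    stop("group_props needs names I, II, III")
  if (ko_delta < 0 || ko_delta > 1 - valley_meth)
    stop("ko_delta must lie in [0, 1 - valley_meth]")
  if (length(dynamic_meth_levels) != length(lineages))
    stop("need one dynamic methylation level per lineage")
  if (any(dynamic_meth_levels < 0 | dynamic_meth_levels > 1))
    stop("dynamic methylation levels must lie in [0, 1]")
  if (tf_fold < 1) stop("tf_fold must be >= 1")
  if (valley_length[1] < 5000)
    stop("valleys must be at least 5 kb (the minimal DMV length)")
  structure(cfg, class = "dmv_sim_config")
}

#' @export
print.dmv_sim_config <- function(x, ...) {
  cat("dmv_sim_config: ", x$n_chrom, " x ",
      format(x$chrom_length, scientific = FALSE), " bp, ",
      x$n_valleys, " valleys (", paste(names(x$group_props),
                                       x$group_props, sep = "=",
                                       collapse = ", "),
      "), coverage lambda = ", x$coverage, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

.sub_seed <- function(config, k) {
  (as.integer(config$seed) * 10L + as.integer(k)) %% 2147483647L
}

#' Simulate the ground truth of a synthetic study
#'
#' Places grid-aligned valleys, CGIs (inside valleys and in the
#' background), tsDMRs (one fully inside each dynamic valley, plus decoys
#' away from valleys), genes (one TSS per valley plus background genes),
#' per-valley lineage methylation levels, per-gene lineage FPKM, Polycomb
#' flags (group I valleys), and the CpG site landscape with background
#' Beta methylation.
#'
#' @param config A [dmv_sim_config()].
#' @return A list of class `dmv_truth` with elements `layout`, `valleys`,
#'   `meth_levels`, `cgis`, `tsdmrs`, `genes`, `fpkm_true`, `sites`,
#'   `config`.
#' @export
simulate_dmv_truth <- function(config) {
  stopifnot(inherits(config, "dmv_sim_config"))
  with_seed(.sub_seed(config, 0), .build_truth(config))
}

.build_truth <- function(cfg) {
  layout <- genome_layout(stats::setNames(rep(cfg$chrom_length, cfg$n_chrom),
                                          paste0("chr", seq_len(cfg$n_chrom))))
  margin <- 25000
  # valleys per chromosome, round-robin
  per_chrom <- table(rep(names(layout), length.out = cfg$n_valleys))
  vall <- list()
  for (chr in names(layout)) {
    k <- as.integer(per_chrom[chr])
    if (is.na(k) || k == 0) next
    lens <- sample(seq(cfg$valley_length[1], cfg$valley_length[2],
                       by = 1000), k, replace = TRUE)
    slack <- unname(layout[chr]) - 2 * margin - sum(lens) -
      (k - 1) * cfg$min_gap
    if (slack < 0)
      stop("chromosome too short for ", k, " valleys; enlarge the genome")
    extra <- slack * diff(c(0, sort(stats::runif(k))))
    starts <- numeric(k)
    pos <- margin
    for (i in seq_len(k)) {
      pos <- pos + extra[i]
      starts[i] <- floor(pos / 1000) * 1000
      pos <- starts[i] + lens[i] + cfg$min_gap
    }
    vall[[chr]] <- data.frame(chrom = chr, start = starts,
                              end = starts + lens,
                              stringsAsFactors = FALSE)
  }
  valleys <- do.call(rbind, vall)
  nv <- nrow(valleys)
  counts <- diff(round(cumsum(c(0, cfg$group_props[c("I", "II", "III")])) * nv))
  grp <- sample(rep(c("I", "II", "III"), counts))
  valleys$id <- sprintf("valley_%03d", seq_len(nv))
  valleys$group <- grp
  valleys$polycomb <- grp == "I"
  rownames(valleys) <- NULL

  # per-valley lineage methylation levels
  nl <- length(cfg$lineages)
  meth_levels <- matrix(cfg$valley_meth, nv, nl,
                        dimnames = list(valleys$id, cfg$lineages))
  for (i in which(grp != "I"))
    meth_levels[i, ] <- sample(cfg$dynamic_meth_levels)
  valleys$peak_lineage <- NA_character_
  valleys$peak_lineage[grp == "II"] <-
    cfg$lineages[apply(meth_levels[grp == "II", , drop = FALSE], 1, which.min)]
  valleys$peak_lineage[grp == "III"] <-
    cfg$lineages[apply(meth_levels[grp == "III", , drop = FALSE], 1, which.max)]

  # CGIs inside valleys: one per equal-width slot, kept off the edges
  cgi_rows <- list()
  for (i in seq_len(nv)) {
    L <- valleys$end[i] - valleys$start[i]
    kc <- cfg$cgis_per_valley
    slot <- (L - 1000) / kc
    for (s in seq_len(kc)) {
      clen <- round(stats::runif(1, cfg$cgi_length[1],
                                 min(cfg$cgi_length[2], slot - 100)))
      if (clen < 200) next
      lo <- valleys$start[i] + 500 + (s - 1) * slot
      off <- floor(stats::runif(1, 0, slot - clen))
      cgi_rows[[length(cgi_rows) + 1]] <-
        data.frame(chrom = valleys$chrom[i], start = lo + off,
                   end = lo + off + clen, in_valley = TRUE,
                   stringsAsFactors = FALSE)
    }
  }
  # background CGIs, kept >= 6 kb away from valleys and from each other
  # background CGIs keep >= 6 kb from valleys AND from each other: a single
  # unmethylated CGI (<= 2 kb) can never pull a 5-kb window mean below the
  # calling threshold, but a close pair can, which would plant an
  # unintended valley outside the truth set
  bg_cgi <- .place_background(cfg$n_background_cgis,
                              round(stats::runif(cfg$n_background_cgis,
                                                 cfg$cgi_length[1],
                                                 cfg$cgi_length[2])),
                              layout, valleys, clearance = 6000,
                              spacing = 6000)
  if (nrow(bg_cgi)) bg_cgi$in_valley <- FALSE
  cgis <- rbind(do.call(rbind, cgi_rows), bg_cgi)
  cgis$name <- sprintf("CGI_%03d", seq_len(nrow(cgis)))
  cgis <- interval_set(cgis, layout = layout)

  # tsDMRs: one strictly inside each dynamic valley, plus decoys outside
  ts_rows <- list()
  for (i in which(grp != "I")) {
    L <- valleys$end[i] - valleys$start[i]
    tlen <- round(stats::runif(1, cfg$tsdmr_length[1],
                               min(cfg$tsdmr_length[2], L - 400)))
    off <- floor(stats::runif(1, 200, L - tlen - 200))
    ts_rows[[length(ts_rows) + 1]] <-
      data.frame(chrom = valleys$chrom[i], start = valleys$start[i] + off,
                 end = valleys$start[i] + off + tlen,
                 stringsAsFactors = FALSE)
  }
  nd <- cfg$n_decoy_tsdmrs
  decoy_len <- c(round(stats::runif(ceiling(nd / 2), 1000, 2000)),
                 round(stats::runif(floor(nd / 2), cfg$tsdmr_length[1],
                                    cfg$tsdmr_length[2])))
  decoys <- .place_background(nd, decoy_len, layout, valleys,
                              clearance = 6000)
  tsdmrs <- rbind(do.call(rbind, ts_rows), decoys)
  tsdmrs$name <- sprintf("tsDMR_%03d", seq_len(nrow(tsdmrs)))
  tsdmrs <- interval_set(tsdmrs, layout = layout)

  # genes: one TSS at each valley midpoint, plus flat background genes
  genes <- data.frame(gene = sprintf("gene_%s", valleys$id),
                      chrom = valleys$chrom,
                      tss = floor((valleys$start + valleys$end) / 2),
                      valley_id = valleys$id, stringsAsFactors = FALSE)
  bg_gene <- .place_background(cfg$n_background_genes,
                               rep(1, cfg$n_background_genes),
                               layout, valleys, clearance = 6000)
  if (nrow(bg_gene))
    genes <- rbind(genes,
                   data.frame(gene = sprintf("gene_bg%03d",
                                             seq_len(nrow(bg_gene))),
                              chrom = bg_gene$chrom, tss = bg_gene$start,
                              valley_id = NA_character_,
                              stringsAsFactors = FALSE))

  # per-gene true lineage FPKM
  fpkm_true <- matrix(0, nrow(genes), nl,
                      dimnames = list(genes$gene, cfg$lineages))
  for (i in seq_len(nrow(genes))) {
    vid <- genes$valley_id[i]
    if (is.na(vid)) {
      fpkm_true[i, ] <- stats::runif(1, 0, 3)
      next
    }
    vi <- match(vid, valleys$id)
    if (valleys$group[vi] == "I") {
      fpkm_true[i, ] <- stats::runif(1, 2, 6)
    } else {
      peak <- match(valleys$peak_lineage[vi], cfg$lineages)
      fpkm_true[i, ] <- stats::runif(nl, cfg$basal_fpkm[1],
                                     cfg$basal_fpkm[2])
      fpkm_true[i, peak] <- stats::runif(1, cfg$peak_fpkm[1],
                                         cfg$peak_fpkm[2])
    }
  }

  sites <- .simulate_sites(cfg, layout, valleys, cgis)

  structure(list(layout = layout, valleys = valleys,
                 meth_levels = meth_levels, cgis = cgis, tsdmrs = tsdmrs,
                 genes = genes, fpkm_true = fpkm_true, sites = sites,
                 config = cfg),
            class = "dmv_truth")
}

# rejection-place n intervals of given lengths outside valleys (with
# clearance) and non-overlapping among themselves
.place_background <- function(n, lens, layout, valleys, clearance,
                              spacing = 200) {
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  cl <- as.numeric(layout)
  cn <- names(layout)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 50 * n) {
    tries <- tries + 1L
    len <- lens[placed + 1L]
    ci <- sample.int(length(cl), 1, prob = cl)
    s <- floor(stats::runif(1, clearance, cl[ci] - len - clearance))
    e <- s + len
    near_valley <- any(valleys$chrom == cn[ci] &
                         valleys$start - clearance < e &
                         valleys$end + clearance > s)
    clash <- nrow(out) > 0 && any(out$chrom == cn[ci] &
                                    out$start < e + spacing &
                                    out$end > s - spacing)
    if (near_valley || clash) next
    out <- rbind(out, data.frame(chrom = cn[ci], start = s, end = e,
                                 stringsAsFactors = FALSE))
    placed <- placed + 1L
  }
  if (placed < n)
    stop("could not place ", n, " background features; genome too crowded")
  out
}

# CpG landscape: geometric background spacing plus dense CGI blocks, with
# per-site annotation and background Beta methylation
.simulate_sites <- function(cfg, layout, valleys, cgis) {
  rows <- list()
  for (chr in names(layout)) {
    L <- unname(layout[chr])
    pos <- numeric(0)
    cur <- 0
    repeat {
      gaps <- stats::rgeom(ceiling(L / cfg$cpg_spacing * 0.5) + 100,
                           1 / cfg$cpg_spacing) + 2
      new <- cur + cumsum(gaps)
      pos <- c(pos, new[new < L])
      if (length(new) == 0 || max(new) >= L) break
      cur <- max(new)
    }
    cg <- cgis[cgis$chrom == chr, , drop = FALSE]
    for (j in seq_len(nrow(cg))) {
      n_in <- ceiling((cg$end[j] - cg$start[j]) / cfg$cgi_spacing)
      gaps <- stats::rgeom(n_in, 1 / cfg$cgi_spacing) + 2
      p <- cg$start[j] + cumsum(gaps)
      pos <- c(pos, p[p < cg$end[j]])
    }
    pos <- sort(unique(pos))
    d <- data.frame(chrom = chr, pos = pos, stringsAsFactors = FALSE)
    d$in_cgi <- .point_in(pos, cg)
    vv <- valleys[valleys$chrom == chr, , drop = FALSE]
    vidx <- .point_which(pos, vv)
    d$valley <- ifelse(is.na(vidx), NA_character_, vv$id[vidx])
    d$base_meth <- stats::rbeta(nrow(d), cfg$background_beta[1],
                                cfg$background_beta[2])
    rows[[chr]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.point_in <- function(pos, ivs) !is.na(.point_which(pos, ivs))

# index of the (disjoint, sorted-by-start) interval containing each point
.point_which <- function(pos, ivs) {
  if (nrow(ivs) == 0) return(rep(NA_integer_, length(pos)))
  o <- order(ivs$start)
  i <- findInterval(pos, ivs$start[o])
  ok <- i > 0 & pos < ivs$end[o][pmax(i, 1)]
  ifelse(ok, o[pmax(i, 1)], NA_integer_)
}

#' True per-CpG methylation of a lineage
#'
#' CGI sites are constitutively low; valley non-CGI sites take the
#' valley's per-lineage level; background sites take their Beta draw.
#'
#' @param truth A [simulate_dmv_truth()] result.
#' @param lineage Lineage label, or `"stem"` for the WT/KO methylome in
#'   which every valley sits at the constant low level.
#' @return Numeric vector aligned with `truth$sites`.
#' @export
true_methylation <- function(truth, lineage) {
  cfg <- truth$config
  s <- truth$sites
  m <- s$base_meth
  in_valley <- !is.na(s$valley)
  if (identical(lineage, "stem")) {
    m[in_valley] <- cfg$valley_meth
  } else {
    stopifnot(lineage %in% cfg$lineages)
    m[in_valley] <- truth$meth_levels[s$valley[in_valley], lineage]
  }
  m[s$in_cgi] <- cfg$cgi_meth
  m
}

# observe a true methylation vector: Poisson coverage, binomial counts,
# zero-coverage sites dropped (as in real data)
.observe <- function(sites, true_m, lambda) {
  total <- stats::rpois(nrow(sites), lambda)
  keep <- total > 0
  meth <- stats::rbinom(sum(keep), total[keep], true_m[keep])
  methyl_calls(data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                          meth = meth, total = total[keep],
                          stringsAsFactors = FALSE))
}

#' Simulate per-lineage methylomes
#'
#' Observed counts per CpG and lineage: total ~ Poisson(lambda) (sites with
#' zero coverage omitted), methylated ~ Binomial(total, true methylation).
#'
#' @param truth A [simulate_dmv_truth()] result.
#' @return Named list of [methyl_calls()], one per lineage.
#' @export
simulate_methylomes <- function(truth) {
  cfg <- truth$config
  with_seed(.sub_seed(cfg, 1), {
    out <- lapply(cfg$lineages, function(l)
      .observe(truth$sites, true_methylation(truth, l), cfg$coverage))
    stats::setNames(out, cfg$lineages)
  })
}

#' Simulate the expression matrix
#'
#' Sample-level FPKM = true lineage FPKM times a mild log-normal factor;
#' dynamic genes satisfy the dynamic-gene rule by construction, background
#' and constant-valley genes violate it.
#'
#' @param truth A [simulate_dmv_truth()] result.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(truth) {
  cfg <- truth$config
  with_seed(.sub_seed(cfg, 2), {
    samples <- paste0(rep(cfg$lineages, each = cfg$samples_per_lineage), "_",
                      seq_len(cfg$samples_per_lineage))
    lin <- stats::setNames(rep(cfg$lineages, each = cfg$samples_per_lineage),
                           samples)
    fpkm <- truth$fpkm_true[, lin, drop = FALSE]
    noise <- exp(stats::rnorm(length(fpkm), 0, cfg$expr_noise_sd))
    fpkm <- fpkm * noise
    colnames(fpkm) <- samples
    expression_matrix(fpkm, lin)
  })
}

#' Simulate a WT/KO methylome pair
#'
#' The WT methylome has every valley at the constant low level. The KO
#' methylome adds `ko_delta` to the true methylation of non-CGI CpGs
#' inside Polycomb-flagged valleys; CGI parts and the background are
#' untouched. Both methylomes are independently resampled.
#'
#' @param truth A [simulate_dmv_truth()] result.
#' @return List with `wt` and `ko` [methyl_calls()].
#' @export
simulate_ko_pair <- function(truth) {
  cfg <- truth$config
  wt_m <- true_methylation(truth, "stem")
  ko_m <- wt_m
  pc <- truth$valleys$id[truth$valleys$polycomb]
  bump <- !is.na(truth$sites$valley) & truth$sites$valley %in% pc &
    !truth$sites$in_cgi
  ko_m[bump] <- pmin(1, ko_m[bump] + cfg$ko_delta)
  with_seed(.sub_seed(cfg, 3), {
    list(wt = .observe(truth$sites, wt_m, cfg$coverage),
         ko = .observe(truth$sites, ko_m, cfg$coverage))
  })
}

#' Simulate feature sets: peaks, TF sites, super-enhancers, CGI scores
#'
#' TF sites follow a Poisson process at `tf_rate`/kb in the background and
#' `tf_fold` times that inside valleys. H3K4me3 peaks sit on the promoters
#' of dynamic valleys, H3K27me3 and EED peaks cover Polycomb valleys, and
#' super-enhancers land on valleys with per-group probability `se_frac`.
#' CGI scores (deamination-rate-like) are drawn lower inside valleys.
#'
#' @param truth A [simulate_dmv_truth()] result.
#' @param tf_fold Override the configured TF enrichment fold (optional).
#' @return List with `tf_sites`, `k4`, `k27`, `eed`, `superenhancers`,
#'   `cgi_scores`.
#' @export
simulate_features <- function(truth, tf_fold = NULL) {
  cfg <- truth$config
  if (is.null(tf_fold)) tf_fold <- cfg$tf_fold
  layout <- truth$layout
  v <- truth$valleys
  with_seed(.sub_seed(cfg, 4), {
    tf <- list()
    for (chr in names(layout)) {
      L <- unname(layout[chr])
      n_bg <- stats::rpois(1, cfg$tf_rate * L / 1000)
      p <- floor(stats::runif(n_bg, 0, L - 8))
      vv <- v[v$chrom == chr, , drop = FALSE]
      for (i in seq_len(nrow(vv))) {
        n_extra <- stats::rpois(1, (tf_fold - 1) * cfg$tf_rate *
                                  (vv$end[i] - vv$start[i]) / 1000)
        p <- c(p, floor(stats::runif(n_extra, vv$start[i], vv$end[i] - 8)))
      }
      if (length(p))
        tf[[chr]] <- data.frame(chrom = chr, start = sort(p),
                                end = sort(p) + 8, stringsAsFactors = FALSE)
    }
    tf_sites <- interval_set(do.call(rbind, tf))

    dyn <- v[v$group != "I", , drop = FALSE]
    mid <- floor((dyn$start + dyn$end) / 2)
    k4 <- interval_set(data.frame(chrom = dyn$chrom,
                                  start = pmax(dyn$start, mid - 1500),
                                  end = pmin(dyn$end, mid + 1500),
                                  name = dyn$id, stringsAsFactors = FALSE))
    pc <- v[v$polycomb, , drop = FALSE]
    k27 <- interval_set(data.frame(chrom = pc$chrom,
                                   start = pmax(0, pc$start - 1000),
                                   end = pmin(unname(layout[pc$chrom]),
                                              pc$end + 1000),
                                   name = pc$id, stringsAsFactors = FALSE))
    eed <- k27

    carry <- stats::runif(nrow(v)) < unname(cfg$se_frac[v$group])
    sev <- v[carry, , drop = FALSE]
    ses <- if (nrow(sev)) {
      m <- floor((sev$start + sev$end) / 2)
      interval_set(data.frame(chrom = sev$chrom, start = m,
                              end = pmin(unname(layout[sev$chrom]),
                                         m + 10000),
                              name = sev$id, stringsAsFactors = FALSE))
    } else interval_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()))

    sc <- as.data.frame(truth$cgis)
    sc$score <- pmax(0, stats::rnorm(nrow(sc),
                                     ifelse(sc$in_valley, 0.08, 0.12),
                                     0.01))
    list(tf_sites = tf_sites, k4 = k4, k27 = k27, eed = eed,
         superenhancers = ses, cgi_scores = sc)
  })
}

#' Simulate a complete synthetic study
#'
#' Truth, per-lineage methylomes, expression matrix, WT/KO pair and
#' feature sets, all reproducible from the config's seed.
#'
#' @param config A [dmv_sim_config()].
#' @return List of class `dmv_study` with elements `truth`, `methylomes`,
#'   `expression`, `ko_pair`, `features`.
#' @export
simulate_dmv_study <- function(config = dmv_sim_config()) {
  truth <- simulate_dmv_truth(config)
  structure(list(truth = truth,
                 methylomes = simulate_methylomes(truth),
                 expression = simulate_expression(truth),
                 ko_pair = simulate_ko_pair(truth),
                 features = simulate_features(truth)),
            class = "dmv_study")
}

#' @export
print.dmv_truth <- function(x, ...) {
  cat("dmv_truth: ", nrow(x$valleys), " planted valleys on ",
      length(x$layout), " chromosome(s); groups: ",
      paste(names(table(x$valleys$group)), table(x$valleys$group),
            sep = "=", collapse = ", "),
      "; ", nrow(x$sites), " CpG sites\n", sep = "")
  invisible(x)
}

#' @export
print.dmv_study <- function(x, ...) {
  print(x$truth)
  cat("lineage methylomes:", paste(names(x$methylomes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a truth directory
#'
#' Writes the planted valleys (BED4 + group TSV), CGIs, tsDMRs, TSS
#' annotations, true per-gene lineage FPKM, and the configuration (YAML if
#' the yaml package is available, otherwise as serialized R code).
#'
#' @param truth A [simulate_dmv_truth()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- truth$valleys
  write_bed(data.frame(chrom = v$chrom, start = v$start, end = v$end,
                       name = v$id), file.path(dir, "valleys.bed"))
  utils::write.table(v, file.path(dir, "valleys.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(truth$cgis, file.path(dir, "cgis.bed"))
  write_bed(truth$tsdmrs, file.path(dir, "tsdmrs.bed"))
  g <- truth$genes
  write_bed(data.frame(chrom = g$chrom, start = g$tss, end = g$tss + 1,
                       name = g$gene), file.path(dir, "tss.bed"))
  utils::write.table(cbind(gene = rownames(truth$fpkm_true),
                           as.data.frame(truth$fpkm_true)),
                     file.path(dir, "fpkm_true.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- truth$config
  cfg$lineages <- as.character(cfg$lineages)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  } else {
    dput(unclass(cfg), file.path(dir, "config.R"))
  }
  invisible(dir)
}
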