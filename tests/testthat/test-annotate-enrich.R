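test_that("chromatin states are exclusive, exhaustive and oracle-consistent", {
  dmvs <- interval_set("chr1", c(0, 20000, 40000, 60000),
                       c(10000, 30000, 50000, 70000))
  dmvs$id <- paste0("d", 1:4)
  k4 <- interval_set("chr1", c(1000, 21000), c(2000, 22000))
  k27 <- interval_set("chr1", c(21000, 41000), c(23000, 42000))
  st <- chromatin_state(dmvs, k4, k27, polycomb_peaks = k27)
  expect_equal(as.character(st$state),
               c("K4-only", "K4+K27", "K27-only", "none"))
  expect_equal(st$polycomb, c(FALSE, TRUE, TRUE, FALSE))

  set.seed(51)
  len <- 1e5
  for (rep in 1:5) {
    dm <- random_disjoint_set(8, len, named = FALSE)
    dm$id <- sprintf("d%02d", seq_len(nrow(dm)))
    a <- random_disjoint_set(10, len, named = FALSE)
    b <- random_disjoint_set(10, len, named = FALSE)
    st <- chromatin_state(dm, a, b)
    am <- mask_of(a, len)
    bm <- mask_of(b, len)
    for (i in seq_len(nrow(dm))) {
      span <- (dm$start[i] + 1):dm$end[i]
      want <- if (any(am[span]) && any(bm[span])) "K4+K27" else
        if (any(am[span])) "K4-only" else
          if (any(bm[span])) "K27-only" else "none"
      expect_equal(as.character(st$state[i]), want)
    }
  }
})

test_that("CGI partition tiles each valley exactly", {
  dmvs <- interval_set("chr1", 0, 10000)
  dmvs$id <- "d1"
  cgis <- interval_set("chr1", c(1000, 5000), c(2000, 6000))
  p <- partition_cgi(dmvs, cgis)
  expect_equal(p$non_cgi$start, c(0, 2000, 6000))
  expect_equal(p$non_cgi$end, c(1000, 5000, 10000))
  expect_equal(sum(p$cgi$end - p$cgi$start), 2000)

  # valley fully inside a CGI -> empty non-CGI part
  d2 <- interval_set("chr1", 3000, 4000)
  d2$id <- "d2"
  p2 <- partition_cgi(d2, interval_set("chr1", 1000, 8000))
  expect_equal(nrow(p2$non_cgi), 0)
  expect_equal(sum(p2$cgi$end - p2$cgi$start), 1000)
})

test_that("methylation change is zero against itself and recovers a shift", {
  set.seed(52)
  n <- 400
  tot <- rpois(n, 20) + 1
  pos <- sort(sample(0:49999, n))
  wt <- methyl_calls(data.frame(chrom = "chr1", pos = pos,
                                meth = rbinom(n, tot, 0.1), total = tot))
  regions <- interval_set("chr1", c(0, 25000), c(20000, 45000))
  regions$id <- c("r1", "r2")
  d0 <- methylation_change(wt, wt, regions)
  expect_equal(d0$delta_m, c(0, 0))
  expect_false(any(d0$hyper))

  ko <- wt
  ko$meth <- rbinom(n, ko$total, 0.4)
  d1 <- methylation_change(wt, ko, regions, hyper_threshold = 0.1)
  expect_true(all(d1$delta_m > 0.2))
  expect_true(all(d1$hyper))
})

test_that("regions without coverage give NA with a warning", {
  wt <- methyl_calls(data.frame(chrom = "chr1", pos = 10, meth = 1,
                                total = 2))
  regions <- interval_set("chr1", c(0, 5000), c(100, 6000))
  regions$id <- c("ok", "empty")
  expect_warning(d <- methylation_change(wt, wt, regions), "without coverage")
  expect_true(is.na(d$delta_m[2]))
})

test_that("meta-profile reproduces the closed-form density", {
  # 10-kb region, 20 midpoints inside, none outside -> mean body density 2/kb
  sites <- interval_set("chr1", seq(30000, 39999, length.out = 20),
                        seq(30000, 39999, length.out = 20) + 1)
  regions <- interval_set("chr1", 30000, 40000)
  p <- site_density_profile(sites, regions, flank_bp = 20000,
                            body_bins = 20, flank_bins = 20)
  expect_equal(mean(p$density[p$zone == "body"]), 2.0)
  expect_equal(sum(p$density[p$zone != "body"]), 0)
  # no sites at all -> all-zero profile
  none <- interval_set(data.frame(chrom = character(), start = numeric(),
                                  end = numeric()))
  p0 <- site_density_profile(none, regions)
  expect_true(all(p0$density == 0))
})

test_that("uniform sites give flat profiles at the global density", {
  set.seed(53)
  len <- 2e6
  n_sites <- 4000  # 2 per kb
  pos <- sort(sample(0:(len - 2), n_sites))
  sites <- interval_set("chr1", pos, pos + 1)
  s <- seq(1e5, 1.7e6, by = 2e5)
  regions <- interval_set("chr1", s, s + 30000)
  p <- site_density_profile(sites, regions, flank_bp = 20000)
  global <- n_sites / (len / 1000)
  expect_equal(mean(p$density[p$zone == "body"]), global, tolerance = 0.15)
  expect_equal(mean(p$density[p$zone != "body"]), global, tolerance = 0.15)
})

test_that("length-matched controls are deterministic and conserve lengths", {
  layout <- genome_layout(c(chr1 = 1e6, chr2 = 5e5))
  regions <- interval_set(c("chr1", "chr1", "chr2"),
                          c(10000, 50000, 1000),
                          c(25000, 56000, 9000))
  regions$id <- paste0("r", 1:3)
  c1 <- random_length_matched_controls(regions, layout, n_draws = 20,
                                       seed = 99)
  c2 <- random_length_matched_controls(regions, layout, n_draws = 20,
                                       seed = 99)
  expect_identical(c1, c2)
  for (d in split(c1, c1$draw))
    expect_setequal(d$end - d$start, regions$end - regions$start)
  expect_true(all(c1$start >= 0))
  expect_true(all(c1$end <= unname(layout[c1$chrom])))
})

test_that("controls avoid excluded regions and error when impossible", {
  layout <- genome_layout(c(chr1 = 1e5))
  regions <- interval_set("chr1", 0, 10000)
  regions$id <- "r1"
  excl <- interval_set("chr1", 0, 50000)
  ctrl <- random_length_matched_controls(regions, layout, n_draws = 50,
                                         seed = 1, exclude = excl)
  expect_true(all(ctrl$start >= 50000))
  full <- interval_set("chr1", 0, 99000)
  expect_error(random_length_matched_controls(regions, layout, seed = 1,
                                              exclude = full,
                                              max_tries = 50),
               "r1")
})

test_that("control densities are unbiased under the uniform model", {
  set.seed(54)
  layout <- genome_layout(c(chr1 = 1e6))
  n_sites <- 2000
  pos <- sort(sample(0:999998, n_sites))
  sites <- interval_set("chr1", pos, pos + 1)
  regions <- interval_set("chr1", c(1e5, 4e5, 7e5), c(1.3e5, 4.2e5, 7.5e5))
  regions$id <- paste0("r", 1:3)
  ctrl <- random_length_matched_controls(regions, layout, n_draws = 1000,
                                         seed = 7)
  dens <- vapply(split(ctrl, ctrl$draw), function(d)
    region_site_density(sites, d), numeric(1))
  global <- n_sites / 1000  # sites per kb
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - global), 3 * se + 0.02)
})

test_that("enrichment p follows the add-one formula and stays in (0, 1]", {
  ctrl <- seq_len(999) / 1000
  expect_equal(enrichment_test(2, ctrl)$p, 1 / 1000)
  low <- enrichment_test(0, ctrl)
  expect_equal(low$p, 1)
  expect_equal(enrichment_test(2, ctrl)$fold, 2 / mean(ctrl))
  z <- suppressWarnings(enrichment_test(1, rep(0, 50)))
  expect_true(is.na(z$fold))
  expect_false(z$fold_defined)
})

test_that("stratified score comparison matches its worked examples", {
  set.seed(55)
  a <- data.frame(cg_density = runif(200, 0, 10), score = runif(200))
  b <- a
  s0 <- stratified_score_compare(a, b, n_strata = 4)
  expect_equal(s0$median[s0$set == "a"], s0$median[s0$set == "b"])
  b2 <- a
  b2$score <- a$score + 0.1
  s1 <- stratified_score_compare(a, b2, n_strata = 4)
  expect_equal(s1$median[s1$set == "b"] - s1$median[s1$set == "a"],
               rep(0.1, 4))
  expect_equal(sum(s1$n[s1$set == "a"]), 200)
})

test_that("overlap percentages per group count any-overlap valleys", {
  dmvs <- interval_set("chr1", c(0, 20000, 40000, 60000),
                       c(10000, 30000, 50000, 70000))
  dmvs$id <- paste0("d", 1:4)
  groups <- factor(c("I", "I", "I", "I"), levels = c("I", "II"))
  feats <- interval_set("chr1", 5000, 6000)
  ov <- overlap_percentage(dmvs, feats, groups)
  expect_equal(ov$pct[ov$group == "I"], 25)
  expect_equal(ov$n[ov$group == "II"], 0)
  expect_true(is.nan(ov$pct[ov$group == "II"]))
  none <- interval_set(data.frame(chrom = character(), start = numeric(),
                                  end = numeric()))
  ov0 <- overlap_percentage(dmvs, none, groups)
  expect_equal(ov0$pct[ov0$group == "I"], 0)
})
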