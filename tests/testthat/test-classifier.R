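test_that("the dynamic-gene rule reproduces its worked examples", {
  expect_true(is_dynamic_gene(c(6, 1, 1, 1)))
  expect_false(is_dynamic_gene(c(5, 2, 2, 2)))   # 5 < 3 * 2
  expect_false(is_dynamic_gene(c(9, 3, 3, 3)))   # rest mean 3 > 2
  expect_false(is_dynamic_gene(c(1.5, 0, 0, 0))) # peak < 2
  expect_error(is_dynamic_gene(c(3, NA, 1, 1)), "non-missing")
  expect_error(is_dynamic_gene(5), "lineage")
})

test_that("scaling all FPKM only acts through the absolute thresholds", {
  f <- c(6, 1, 1, 1)
  # scaling preserves the fold ratio, so only min_peak / max_rest_mean can
  # flip the outcome
  expect_true(is_dynamic_gene(f * 1.5))
  expect_false(is_dynamic_gene(f * 3))     # rest mean 3 > 2
  expect_false(is_dynamic_gene(f * 0.25))  # peak 1.5 < 2
  set.seed(41)
  for (i in 1:50) {
    f <- runif(4, 0, 10)
    c_ <- runif(1, 1, 4)
    base <- is_dynamic_gene(f)
    scaled <- is_dynamic_gene(f * c_)
    # with thresholds disabled the rule is exactly scale-invariant
    expect_equal(is_dynamic_gene(f, min_peak = 0, max_rest_mean = Inf),
                 is_dynamic_gene(f * c_, min_peak = 0, max_rest_mean = Inf))
  }
})

test_that("the dynamic-valley rule handles containment, coverage and straddle", {
  dmv <- interval_set("chr1", 10000, 20000)
  dmv$id <- "d1"
  # fully contained 2.5-kb tsDMR
  expect_true(is_dynamic_dmv(dmv, interval_set("chr1", 12000, 14500))$dynamic)
  # 6000 bp covered, none fully inside: 0.6 > 0.5
  ts2 <- interval_set("chr1", c(8000, 17000), c(14000, 24000))
  expect_true(is_dynamic_dmv(dmv, ts2)$dynamic)
  # one straddling tsDMR covering 3000 bp: no containment, 0.3 <= 0.5
  ts3 <- interval_set("chr1", 9000, 13000)
  expect_false(is_dynamic_dmv(dmv, ts3)$dynamic)
  # tsDMRs of exactly 2 kb are excluded (strict length filter)
  expect_false(is_dynamic_dmv(dmv, interval_set("chr1", 13000, 15000))$dynamic)
  # exactly half coverage is not "more than half"
  expect_false(is_dynamic_dmv(dmv, interval_set("chr1", 5000, 15000),
                              min_tsdmr_len = 100)$dynamic)
})

test_that("genes associate by TSS with a half-open boundary", {
  dmvs <- interval_set("chr1", 5000, 15000)
  dmvs$id <- "d1"
  tss <- interval_set("chr1", c(7000, 15000, 4999),
                      c(7001, 15001, 5000),
                      name = c("inA", "atEnd", "justBefore"))
  g <- associate_genes(dmvs, tss)
  expect_equal(g$gene, "inA")
  g2 <- associate_genes(dmvs, tss, max_dist = 2)
  expect_setequal(g2$gene, c("inA", "atEnd", "justBefore"))
})

test_that("TSS association matches a brute-force scan on random placements", {
  set.seed(42)
  dmvs <- random_disjoint_set(10, 1e5, named = FALSE)
  dmvs$id <- sprintf("d%02d", seq_len(nrow(dmvs)))
  pos <- sample(0:99999, 200)
  tss <- interval_set("chr1", pos, pos + 1, name = sprintf("g%03d", 1:200))
  got <- associate_genes(dmvs, tss)
  want <- 0L
  for (i in seq_len(nrow(dmvs)))
    want <- want + sum(tss$start >= dmvs$start[i] & tss$start < dmvs$end[i])
  expect_equal(nrow(got), want)
  for (k in seq_len(nrow(got))) {
    d <- dmvs[dmvs$id == got$id[k], ]
    expect_true(got$tss_pos[k] >= d$start && got$tss_pos[k] < d$end)
  }
})

test_that("methylation-expression correlation behaves at the extremes", {
  m <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(meth_expr_correlation(m, 2 + 10 * m), 1)
  expect_equal(meth_expr_correlation(m, 2 - 10 * m), -1)
  expect_true(is.na(meth_expr_correlation(c(0.1, 0.1, 0.1), c(1, 2, 3))))
  expect_error(meth_expr_correlation(c(0.1, 0.2), c(1, 2)), "3")
  # textbook formula recomputation
  set.seed(43)
  for (i in 1:20) {
    a <- runif(4)
    b <- runif(4)
    r_hand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(meth_expr_correlation(a, b), r_hand, tolerance = 1e-12)
  }
})

# three valleys: one constant, one with a contained tsDMR and an
# anticorrelated dynamic gene, one positively correlated
toy_classification <- function(meth2 = c(0.10, 0.20, 0.30, 0.40),
                               meth3 = c(0.40, 0.10, 0.10, 0.10)) {
  dmvs <- interval_set("chr1", c(0, 20000, 40000),
                       c(10000, 30000, 50000))
  dmvs$id <- c("d1", "d2", "d3")
  tsdmrs <- interval_set("chr1", c(22000, 42000), c(25000, 45000))
  lin <- c("blood", "endoderm", "mesoderm", "ectoderm")
  meth <- rbind(d1 = c(0.05, 0.05, 0.05, 0.05), d2 = meth2, d3 = meth3)
  colnames(meth) <- lin
  fpkm <- rbind(gA = rep(c(8, 2, 1, 1), each = 1),
                gB = c(8, 1, 1, 1))
  samples <- paste0(lin, "_1")
  colnames(fpkm) <- samples
  expr <- expression_matrix(fpkm, stats::setNames(lin, samples))
  gene_map <- data.frame(id = c("d2", "d3"), gene = c("gA", "gB"))
  classify_dmvs(dmvs, tsdmrs, meth, expr, gene_map)
}

test_that("classification follows correlation sign with group-I precedence", {
  cls <- toy_classification()
  expect_equal(as.character(cls$label), c("I", "II", "III"))
  expect_true(cls$r[2] < 0)
  expect_true(cls$r[3] > 0)
  # no tsDMR overlap wins over any expression pattern
  expect_false(cls$dynamic[1])
  # labels partition the set
  expect_equal(sum(table(cls$label)), nrow(cls))
})

test_that("classification is invariant to jointly permuting lineages", {
  lin <- c("blood", "endoderm", "mesoderm", "ectoderm")
  perm <- c(3, 1, 4, 2)
  cls1 <- toy_classification()
  cls2 <- toy_classification(meth2 = c(0.10, 0.20, 0.30, 0.40)[perm],
                             meth3 = c(0.40, 0.10, 0.10, 0.10)[perm])
  # permuting methylation alone flips nothing here because expression must
  # move with it; rebuild with both permuted
  dmvs <- interval_set("chr1", c(0, 20000), c(10000, 30000))
  dmvs$id <- c("d1", "d2")
  tsdmrs <- interval_set("chr1", 22000, 25000)
  meth <- rbind(d1 = rep(0.05, 4), d2 = c(0.10, 0.20, 0.30, 0.40))
  fpkm <- rbind(gA = c(8, 2, 1, 1))
  build <- function(ord) {
    m <- meth[, ord, drop = FALSE]
    colnames(m) <- lin
    f <- fpkm[, ord, drop = FALSE]
    samples <- paste0(lin, "_1")
    colnames(f) <- samples
    classify_dmvs(dmvs, tsdmrs, m,
                  expression_matrix(f, stats::setNames(lin, samples)),
                  data.frame(id = "d2", gene = "gA"))
  }
  expect_equal(as.character(build(1:4)$label),
               as.character(build(perm)$label))
  expect_equal(build(1:4)$r, build(perm)$r)
})

test_that("dynamic valleys without a dynamic gene stay unassigned", {
  dmvs <- interval_set("chr1", 0, 10000)
  dmvs$id <- "d1"
  tsdmrs <- interval_set("chr1", 2000, 5000)
  lin <- c("blood", "endoderm", "mesoderm", "ectoderm")
  meth <- matrix(c(0.1, 0.2, 0.3, 0.4), 1, dimnames = list("d1", lin))
  fpkm <- matrix(c(3, 3, 3, 3), 1,
                 dimnames = list("gFlat", paste0(lin, "_1")))
  expr <- expression_matrix(fpkm, stats::setNames(lin, paste0(lin, "_1")))
  cls <- classify_dmvs(dmvs, tsdmrs, meth, expr,
                       data.frame(id = "d1", gene = "gFlat"))
  expect_equal(as.character(cls$label), "dynamic-unassigned")
})

test_that("missing lineage methylation is an error naming the valley", {
  dmvs <- interval_set("chr1", 0, 10000)
  dmvs$id <- "d1"
  lin <- c("blood", "endoderm", "mesoderm", "ectoderm")
  meth <- matrix(NA_real_, 1, 4, dimnames = list("d1", lin))
  fpkm <- matrix(1, 1, 4, dimnames = list("g", paste0(lin, "_1")))
  expr <- expression_matrix(fpkm, stats::setNames(lin, paste0(lin, "_1")))
  expect_error(classify_dmvs(dmvs, interval_set("chr1", 1, 2), meth, expr,
                             data.frame(id = character(),
                                        gene = character())),
               "d1")
})
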