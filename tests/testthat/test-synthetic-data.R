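test_that("the whole study is reproducible from (config, seed)", {
  cfg <- tiny_config(seed = 17)
  s1 <- simulate_dmv_study(cfg)
  s2 <- simulate_dmv_study(cfg)
  expect_identical(s1$truth$valleys, s2$truth$valleys)
  expect_identical(s1$truth$sites, s2$truth$sites)
  expect_identical(s1$methylomes, s2$methylomes)
  expect_identical(s1$expression$fpkm, s2$expression$fpkm)
  expect_identical(s1$ko_pair, s2$ko_pair)
  expect_identical(s1$features$tf_sites, s2$features$tf_sites)
  # a different seed changes the data
  s3 <- simulate_dmv_study(tiny_config(seed = 18))
  expect_false(identical(s1$truth$valleys$start, s3$truth$valleys$start))
})

test_that("planted valleys respect the caller's resolving assumptions", {
  for (seed in c(2, 9, 30)) {
    tr <- simulate_dmv_truth(tiny_config(seed = seed))
    v <- tr$valleys
    expect_true(all(v$end - v$start >= 5000))
    expect_true(all(v$start %% 1000 == 0 & v$end %% 1000 == 0))
    byc <- split(v, v$chrom)
    for (d in byc) {
      d <- d[order(d$start), ]
      if (nrow(d) > 1)
        expect_true(all(d$start[-1] - d$end[-nrow(d)] >= 5000))
    }
    # every dynamic valley holds a contained tsDMR > 2 kb
    dyn <- v[v$group != "I", ]
    for (i in seq_len(nrow(dyn))) {
      inside <- tr$tsdmrs$chrom == dyn$chrom[i] &
        tr$tsdmrs$start >= dyn$start[i] & tr$tsdmrs$end <= dyn$end[i]
      expect_true(any(inside & (tr$tsdmrs$end - tr$tsdmrs$start) > 2000))
    }
  }
})

test_that("observed coverage matches the Poisson rate", {
  cfg <- tiny_config(seed = 3)
  study <- simulate_dmv_study(cfg)
  calls <- study$methylomes$blood
  expect_gt(nrow(calls), 1e4)
  se <- sqrt(cfg$coverage / nrow(calls))
  expect_lt(abs(mean(calls$total) - cfg$coverage), 3 * se + 0.01)
})

test_that("group-I valleys are deeply hypomethylated in every lineage", {
  study <- simulate_dmv_study(tiny_config(seed = 3))
  v <- study$truth$valleys
  g1 <- v[v$group == "I", ]
  for (lin in names(study$methylomes)) {
    m <- mean_methylation(study$methylomes[[lin]], g1)
    expect_true(all(m < 0.15))
  }
})

test_that("group II/III methylation orders with expression as planted", {
  tr <- simulate_dmv_truth(tiny_config(seed = 12))
  v <- tr$valleys
  for (i in which(v$group == "II")) {
    lev <- tr$meth_levels[v$id[i], ]
    expect_equal(names(which.min(lev)), v$peak_lineage[i])
  }
  for (i in which(v$group == "III")) {
    lev <- tr$meth_levels[v$id[i], ]
    expect_equal(names(which.max(lev)), v$peak_lineage[i])
  }
})

test_that("generated expression satisfies the dynamic-gene rule by design", {
  tr <- simulate_dmv_truth(tiny_config(seed = 12))
  expr <- simulate_expression(tr)
  em <- lineage_means(expr)
  v <- tr$valleys
  for (i in seq_len(nrow(v))) {
    g <- tr$genes$gene[match(v$id[i], tr$genes$valley_id)]
    if (v$group[i] == "I") {
      expect_false(is_dynamic_gene(em[g, ]))
    } else {
      expect_true(is_dynamic_gene(em[g, ]))
      expect_equal(colnames(em)[which.max(em[g, ])], v$peak_lineage[i])
    }
  }
  # flat background genes fail the rule
  bg <- tr$genes$gene[is.na(tr$genes$valley_id)]
  expect_false(any(vapply(bg, function(g) is_dynamic_gene(em[g, ]),
                          logical(1))))
})

test_that("classification on noiseless truth recovers every planted label", {
  tr <- simulate_dmv_truth(tiny_config(seed = 20))
  lin <- tr$config$lineages
  expr0 <- expression_matrix(tr$fpkm_true, stats::setNames(lin, lin))
  gene_map <- data.frame(id = tr$genes$valley_id, gene = tr$genes$gene)
  gene_map <- gene_map[!is.na(gene_map$id), ]
  cls <- classify_dmvs(tr$valleys, tr$tsdmrs, tr$meth_levels, expr0,
                       gene_map)
  expect_equal(as.character(cls$label), tr$valleys$group)
})

test_that("the KO pair plants hypermethylation only on non-CGI valley parts", {
  cfg <- tiny_config(seed = 6)
  tr <- simulate_dmv_truth(cfg)
  pair <- simulate_ko_pair(tr)
  pc <- tr$valleys[tr$valleys$polycomb, ]
  ch <- suppressWarnings(methylation_change(pair$wt, pair$ko, pc, tr$cgis))
  # per-valley tolerance: the smallest (5-kb) valleys carry only a few
  # hundred reads on their non-CGI part at lambda = 20, so allow ~3 SD
  expect_true(all(abs(ch$delta_non_cgi - cfg$ko_delta) < 0.09))
  expect_lt(abs(mean(ch$delta_non_cgi) - cfg$ko_delta), 0.04)
  expect_true(all(abs(ch$delta_cgi) < 0.05))
  # non-Polycomb valleys are untouched
  other <- tr$valleys[!tr$valleys$polycomb, ]
  ch2 <- suppressWarnings(methylation_change(pair$wt, pair$ko, other,
                                             tr$cgis))
  expect_true(all(abs(ch2$delta_m) < 0.05))
})

test_that("a zero KO effect leaves the two methylomes at the same level", {
  cfg <- tiny_config(seed = 6, ko_delta = 0)
  tr <- simulate_dmv_truth(cfg)
  pair <- simulate_ko_pair(tr)
  ch <- suppressWarnings(methylation_change(pair$wt, pair$ko,
                                            tr$valleys, tr$cgis))
  expect_true(all(abs(ch$delta_m) < 0.05, na.rm = TRUE))
})

test_that("CGI blocks beat the background CpG density by construction", {
  tr <- simulate_dmv_truth(tiny_config(seed = 4))
  cg <- tr$cgis
  dens_cgi <- cg_density(cg, tr$sites)
  flank <- data.frame(chrom = cg$chrom, start = pmax(0, cg$start - 5000),
                      end = cg$start)
  flank <- flank[flank$end - flank$start > 1000, ]
  dens_flank <- cg_density(flank, tr$sites)
  expect_gt(min(dens_cgi), max(dens_flank))
})

test_that("feature simulation is seed-stable and enrichment responds to fold", {
  tr <- simulate_dmv_truth(tiny_config(seed = 8))
  f1 <- simulate_features(tr)
  f2 <- simulate_features(tr)
  expect_identical(f1$tf_sites, f2$tf_sites)
  e3 <- tf_site_enrichment(simulate_features(tr, tf_fold = 3)$tf_sites,
                           tr$valleys, tr$layout, n_draws = 200, seed = 1)
  expect_lt(e3$p, 0.05)
  expect_gt(e3$fold, 1.5)
  # CGI scores are drawn lower inside valleys
  sc <- f1$cgi_scores
  expect_lt(median(sc$score[sc$in_valley]), median(sc$score[!sc$in_valley]))
})

test_that("generated data round-trip through the package readers", {
  tr <- simulate_dmv_truth(tiny_config(seed = 5))
  study_dir <- tempfile()
  write_truth(tr, study_dir)
  v <- read_bed(file.path(study_dir, "valleys.bed"))
  expect_equal(v$start, sort(tr$valleys$start))
  cg <- read_bed(file.path(study_dir, "cgis.bed"))
  expect_equal(nrow(cg), nrow(tr$cgis))
  calls <- simulate_methylomes(tr)$blood
  f <- tempfile()
  write_methyl_calls(calls, f)
  back <- read_methyl_calls(f, "bedgraph-counts")
  expect_equal(as.data.frame(back), as.data.frame(calls))
})

test_that("invalid configurations are rejected", {
  expect_error(dmv_sim_config(group_props = c(I = 0.5, II = 0.5, III = 0.2)),
               "sum to 1")
  expect_error(dmv_sim_config(ko_delta = 0.99), "ko_delta")
  expect_error(dmv_sim_config(tf_fold = 0.5), "tf_fold")
  expect_error(dmv_sim_config(valley_length = c(3000, 10000)), "5 kb")
})
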