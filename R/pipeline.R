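# End-to-end driver: simulate (or accept) a study, bin each lineage, call
# valleys, merge them into a reference set, classify, annotate, quantify
# the KO effect and TF-site enrichment, and write a report bundle. The run
# is a pure function of (inputs, config, seed).

#' Run the full valley analysis pipeline on a simulated study
#'
#' Stages: simulate -> bin (1-kb, coverage >= 5) -> call valleys per
#' lineage -> union-merge into a reference valley set -> classify into
#' groups I/II/III -> annotate (chromatin state, super-enhancer overlap,
#' KO methylation change on CGI / non-CGI parts, TF-site meta-profile and
#' enrichment) -> write BED/TSV outputs and a versioned summary JSON. All
#' thresholds are echoed into the summary so every number is traceable.
#'
#' @param config A [dmv_sim_config()] describing the study.
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param window,step,max_meth,min_covered_bins Caller parameters, see
#'   [call_dmvs()].
#' @param hyper_threshold KO hypermethylation cutoff, see
#'   [methylation_change()].
#' @param n_control_draws Control draws for the TF enrichment test
#'   (default 500).
#' @return List of class `dmv_pipeline_result`: `study`, `dmvs`
#'   (reference set with per-lineage calls in `per_lineage`),
#'   `classification`, `chromatin`, `se_overlap`, `ko_change`,
#'   `tf_profile`, `tf_enrichment`, `recovery`, `summary`.
#' @export
run_dmv_pipeline <- function(config = dmv_sim_config(), out_dir = NULL,
                             window = 5000, step = 1000, max_meth = 0.15,
                             min_covered_bins = 3, hyper_threshold = 0.1,
                             n_control_draws = 500) {
  message("[1/6] simulating study (seed ", config$seed, ")")
  study <- simulate_dmv_study(config)
  truth <- study$truth
  layout <- truth$layout

  message("[2/6] binning and calling valleys in ",
          length(study$methylomes), " lineages")
  per_lineage <- lapply(study$methylomes, function(cl) {
    tr <- bin_methylation(cl, layout, width = 1000, min_total_coverage = 5)
    call_dmvs(tr, window = window, step = step, max_meth = max_meth,
              min_covered_bins = min_covered_bins)
  })
  pooled <- do.call(rbind, lapply(per_lineage, function(d)
    as.data.frame(d)[, c("chrom", "start", "end")]))
  dmvs <- if (nrow(pooled)) {
    u <- interval_union(interval_set(pooled))
    u$id <- sprintf("DMV_%04d", seq_len(nrow(u)))
    u
  } else {
    interval_set(data.frame(chrom = character(), start = numeric(),
                            end = numeric(), id = character()))
  }
  message("  ", nrow(dmvs), " reference valleys")

  message("[3/6] classifying valleys")
  if (nrow(dmvs)) {
    meth_lin <- dmv_lineage_methylation(dmvs, study$methylomes)
    tss <- interval_set(data.frame(chrom = truth$genes$chrom,
                                   start = truth$genes$tss,
                                   end = truth$genes$tss + 1,
                                   name = truth$genes$gene,
                                   stringsAsFactors = FALSE))
    gene_map <- associate_genes(dmvs, tss)
    cls <- classify_dmvs(dmvs, truth$tsdmrs, meth_lin, study$expression,
                         gene_map)
  } else {
    cls <- classify_dmvs(dmvs[0, ], truth$tsdmrs,
                         matrix(numeric(0), 0, length(config$lineages),
                                dimnames = list(NULL, config$lineages)),
                         study$expression,
                         data.frame(id = character(), gene = character()))
  }

  message("[4/6] annotating valleys")
  chrom_st <- chromatin_state(dmvs, study$features$k4, study$features$k27,
                              study$features$eed)
  se_ov <- if (nrow(dmvs))
    overlap_percentage(dmvs, study$features$superenhancers, cls$label) else
      NULL
  ko <- if (nrow(dmvs))
    suppressWarnings(methylation_change(study$ko_pair$wt, study$ko_pair$ko,
                                        dmvs, truth$cgis,
                                        hyper_threshold)) else NULL

  message("[5/6] TF-site profile and enrichment (", n_control_draws,
          " control draws)")
  tf_prof <- if (nrow(dmvs))
    site_density_profile(study$features$tf_sites, dmvs) else NULL
  tf_enr <- if (nrow(dmvs))
    tf_site_enrichment(study$features$tf_sites, dmvs, layout,
                       n_draws = n_control_draws,
                       seed = .sub_seed(config, 5)) else NULL

  recov <- valley_recovery(truth$valleys, dmvs)

  group_counts <- as.list(table(cls$label))
  pct_by_group <- function(flag) {
    vapply(levels(cls$label), function(g) {
      sel <- cls$label == g & !is.na(ko$delta_m)
      if (!any(sel)) return(NA_real_)
      100 * mean(flag[sel])
    }, numeric(1))
  }
  hyper_by_group <- if (!is.null(ko)) pct_by_group(ko$hyper) else NULL
  hyper_noncgi_by_group <- if (!is.null(ko) && !is.null(ko$hyper_non_cgi))
    pct_by_group(ko$hyper_non_cgi) else NULL

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    params = list(window = window, step = step, max_meth = max_meth,
                  min_covered_bins = min_covered_bins,
                  hyper_threshold = hyper_threshold,
                  n_control_draws = n_control_draws,
                  bin_width = 1000, min_total_coverage = 5),
    n_dmvs = nrow(dmvs),
    group_counts = group_counts,
    pct_hypermethylated_by_group = as.list(hyper_by_group),
    pct_hypermethylated_non_cgi_by_group = as.list(hyper_noncgi_by_group),
    se_overlap_pct_by_group = if (!is.null(se_ov))
      stats::setNames(as.list(se_ov$pct), se_ov$group) else NULL,
    mean_truth_jaccard = recov$mean_jaccard,
    n_false_valleys = recov$n_false,
    tf_enrichment = if (!is.null(tf_enr))
      list(p = tf_enr$p, fold = tf_enr$fold) else NULL)

  res <- structure(list(study = study, dmvs = dmvs,
                        per_lineage = per_lineage, classification = cls,
                        chromatin = chrom_st, se_overlap = se_ov,
                        ko_change = ko, tf_profile = tf_prof,
                        tf_enrichment = tf_enr, recovery = recov,
                        summary = summary),
                   class = "dmv_pipeline_result")

  if (!is.null(out_dir)) {
    message("[6/6] writing report bundle to ", out_dir)
    write_pipeline_bundle(res, out_dir)
  } else {
    message("[6/6] no output directory given; skipping writes")
  }
  res
}

#' Write the pipeline report bundle
#'
#' @param res A [run_dmv_pipeline()] result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  write_bed(res$dmvs, file.path(out_dir, "dmvs.bed"))
  tsv(as.data.frame(res$classification), "classification.tsv")
  tsv(res$chromatin, "chromatin_state.tsv")
  if (!is.null(res$se_overlap)) tsv(res$se_overlap, "se_overlap.tsv")
  if (!is.null(res$ko_change)) tsv(res$ko_change, "methylation_change.tsv")
  if (!is.null(res$tf_profile))
    tsv(as.data.frame(res$tf_profile), "tf_profile.tsv")
  if (!is.null(res$tf_enrichment))
    tsv(data.frame(observed = res$tf_enrichment$observed,
                   control_mean = res$tf_enrichment$control_mean,
                   fold = res$tf_enrichment$fold,
                   p = res$tf_enrichment$p,
                   n_controls = res$tf_enrichment$n_controls),
        "tf_enrichment.tsv")
  write_truth(res$study$truth, file.path(out_dir, "truth"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.dmv_pipeline_result <- function(x, ...) {
  cat("dmv_pipeline_result:", x$summary$n_dmvs, "valleys;",
      "mean truth Jaccard", signif(x$summary$mean_truth_jaccard, 3), "\n")
  print(table(x$classification$label))
  invisible(x)
}
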