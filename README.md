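# dmvscan

Detection, classification and annotation of **DNA methylation valleys
(DMVs)** from whole-genome bisulfite methylomes.

DMVs are large (≥ 5 kb) stretches of near-zero CpG methylation that blanket
the promoters of key developmental regulators (e.g. *Pax6*, *Foxa1*,
*Gata2*). Unlike ordinary CpG islands they extend far beyond the island
itself, are dense in transcription-factor binding sites, and are guarded by
Polycomb: when PRC2 is lost, the non-island portions of Polycomb-bound
valleys gain DNA methylation. `dmvscan` provides a tested, reusable R
implementation of this analysis for people working with per-CpG
methylation calls, lineage-resolved expression tables and standard BED
interval sets — plus a seeded synthetic-methylome generator with known
truth, so every stage can be validated end to end without any large
external dataset.

## The method

**Calling.** Per-CpG calls (methylated count *m*, total count *t*) are
averaged into 1-kb bins, β = Σm / Σt, with bins of summed coverage < 5
treated as missing. A 5-kb window slides in 1-kb steps; a window qualifies
when it holds ≥ 3 covered bins and its mean methylation over covered bins
is **< 0.15**. Overlapping and book-ended qualifying windows are merged, so
every reported valley is ≥ 5 kb.

**Classification.** Valleys overlapping tissue-specific differentially
methylated regions (tsDMRs, > 2 kb) — one contained entirely, or more than
half of the valley covered — are *dynamic*; the rest are constant
(**group I**). For each dynamic valley, genes whose TSS falls inside it are
tested with the dynamic-gene rule: peak lineage FPKM ≥ 2, mean of the other
lineages ≤ 2, peak ≥ 3× that mean. The sign of the Pearson correlation
between per-lineage mean methylation and FPKM across the four lineages
(blood, endoderm, mesoderm, ectoderm) assigns **group II** (r < 0) or
**group III** (r > 0); dynamic valleys with no dynamic gene or an undefined
correlation are reported as `dynamic-unassigned`, never forced.

**Annotation.** Chromatin state by any-overlap with H3K4me3 / H3K27me3
peaks (EED overlap flags Polycomb valleys); CGI / non-CGI partition of each
valley; knockout-vs-wild-type methylation change Δm = m_KO − m_WT computed
separately on CGI and non-CGI parts; TF-binding-site density meta-profiles
(scaled valley body + fixed flanks) against length-matched random control
regions with an add-one empirical enrichment test; RPKM and genome-wide
Z-score normalization for ChIP signal and quantile normalization + log2
for expression tables.

## Worked example

A complete run on a small simulated study (one 2-Mb chromosome, ten
planted valleys, Poisson coverage λ = 30):

```r
library(dmvscan)

cfg   <- dmv_sim_config(seed = 1, n_chrom = 1, chrom_length = 2e6,
                        n_valleys = 10, n_background_cgis = 12,
                        n_background_genes = 8)
study <- simulate_dmv_study(cfg)

track <- bin_methylation(study$methylomes$blood, study$truth$layout,
                         width = 1000, min_total_coverage = 5)
dmvs  <- call_dmvs(track)
dmvs
#> dmv_set: 10 valley(s) (window 5000 bp, step 1000 bp, mean < 0.15)
#>    chrom   start     end       id  mean_meth n_covered_bins
#> 1   chr1  471000  484000 DMV_0001 0.02145095             13
#> 2   chr1  648000  662000 DMV_0002 0.02521160             14
#> ...
summary(dmvs)
#>    n min_len q25_len median_len q75_len max_len total_bp
#> 1 10   11000   13250      15000   19000   28000   169000
```

All ten planted valleys are recovered, with mean methylation ~0.02 inside
each (the background sits near 0.8, so no false windows qualify).
Classification from the four lineage methylomes and the expression matrix:

```r
meth <- dmv_lineage_methylation(dmvs, study$methylomes)
tss  <- interval_set(data.frame(chrom = study$truth$genes$chrom,
                                start = study$truth$genes$tss,
                                end   = study$truth$genes$tss + 1,
                                name  = study$truth$genes$gene))
cls  <- classify_dmvs(dmvs, study$truth$tsdmrs, meth, study$expression,
                      associate_genes(dmvs, tss))
cls
#> dmv_classification: 10 valleys
#>                  I                 II                III dynamic-unassigned
#>                  7                  2                  1                  0
```

Seven constant valleys, two whose methylation falls where their gene is
expressed (group II), one rising with expression (group III) — exactly the
planted labels. The knockout comparison shows the methylation gain is
confined to non-island valley parts, and TF sites are enriched in valleys
relative to length-matched random controls:

```r
ko <- methylation_change(study$ko_pair$wt, study$ko_pair$ko, dmvs,
                         study$truth$cgis)
round(colMeans(ko[cls$label == "I", c("delta_cgi", "delta_non_cgi")]), 3)
#>     delta_cgi delta_non_cgi
#>         0.000         0.299

tf_site_enrichment(study$features$tf_sites, dmvs, study$truth$layout,
                   n_draws = 500, seed = 99)
#> enrichment test: observed 1.349/kb vs 500 controls (mean 0.5659/kb)
#>   fold = 2.384, empirical p = 0.001996
```

The planted KO gain was 0.3 on non-CGI parts (recovered: 0.299, with CGI
parts unchanged) and the planted TF enrichment fold was 3 over a
background that also runs through the valleys, giving an observed
region-vs-genome fold of ~2.4 at the smallest attainable empirical p.

`run_dmv_pipeline()` chains all of the above (simulate → bin → call →
classify → annotate → report) and writes a BED/TSV/JSON report bundle.

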