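---
title: "Calling and classifying DNA methylation valleys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying DNA methylation valleys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmvscan)
```

# The problem

DNA methylation valleys (DMVs) are unusually large hypomethylated domains
— at least 5 kb of near-zero CpG methylation — that cover the promoters of
master developmental regulators. They extend well beyond the CpG island at
the promoter, are dense in transcription-factor binding sites, and many of
them are Polycomb targets whose non-island portions gain methylation when
PRC2 is disabled. `dmvscan` implements the complete desk-side analysis:
calling valleys from per-CpG bisulfite counts, classifying them by their
behaviour across tissue lineages, annotating them against standard
interval sets, and quantifying knockout effects — together with a
synthetic-data generator that plants all of these structures with known
truth.

# The calling model and its assumptions

Input is a set of per-CpG records (chromosome, position, methylated reads
$m_i$, total reads $t_i$), 0-based and strand-merged. Binning computes for
every 1-kb bin the coverage-weighted level

$$\beta_b = \frac{\sum_{i \in b} m_i}{\sum_{i \in b} t_i},$$

with a bin treated as *missing* when $\sum t_i < 5$ or it holds no CpG.
Using the pooled-count ratio rather than the mean of per-site ratios means
well-covered sites dominate poorly covered ones; a flag
(`weighted = FALSE` in `bin_methylation()`) switches to the unweighted
mean for sensitivity analysis.

A 5-kb window then slides in 1-kb steps. A window *qualifies* when

* it holds at least `min_covered_bins = 3` covered bins, and
* the unweighted mean of its covered bin values is strictly below
  `max_meth = 0.15`.

Qualifying windows are merged — overlapping windows always, book-ended
windows (end of one equals start of the next) by default
(`merge_bookended`) — and each merged region runs from the start of its
first qualifying window to the end of its last, so every call is at least
one window (5 kb) long. Windows with fewer than 3 covered bins are
*skipped*: they neither qualify nor interrupt a valley. This choice
prevents valleys being called from one or two poorly covered bins while
tolerating short CpG deserts inside real valleys; it is configurable
because the treatment of missing bins inside windows is a genuine
modelling choice rather than something the calling definition pins down.
Chromosome tails shorter than one window are never scanned, and strict
inequality at the 0.15 ceiling is taken literally.

Key parameters, all in bp or methylation fraction:

| parameter            | default | meaning |
|----------------------|---------|---------|
| bin width            | 1000    | resolution of the scan; boundaries snap to this grid |
| `min_total_coverage` | 5       | summed CpG read coverage below which a bin is missing |
| `window` / `step`    | 5000 / 1000 | scan geometry; bin width must divide both |
| `max_meth`           | 0.15    | strict ceiling on the window mean |
| `min_covered_bins`   | 3       | covered bins needed before a window is assessed |

The same ≥ 5 coverage filter is applied to the 1-kb calling track as to
the 200-bp QC track: calling valleys from near-uncovered kilobases is
worse than leaving the bins missing.

# Classification across lineages

A valley is **dynamic** when tsDMRs longer than 2 kb (strict) either (a)
contain at least one tsDMR entirely inside the valley, or (b) cover more
than half (strict) of its bp. Everything else is constant, **group I**,
regardless of expression — the tsDMR rule takes precedence.

For dynamic valleys, candidate genes are those whose TSS falls inside the
valley (half-open; `max_dist` extends the search window, default 0 because
the valleys are promoter-anchored). A gene is *dynamically expressed* when
its highest per-lineage mean FPKM is ≥ 2, the mean of the other three
lineages is ≤ 2, and the peak is ≥ 3× that mean. The Pearson correlation
$r$ between the valley's four per-lineage mean methylation values and the
gene's four per-lineage mean FPKM values then decides: $r < 0$ gives
**group II**, $r > 0$ **group III**.

With only four points, $|r|$ is weakly determined, so only its sign is
used and no significance test is attempted; $|r|$ is reported as evidence.
When several associated genes pass the dynamic rule, the one with the
largest $|r|$ is used; exact ties with conflicting signs, an undefined
correlation (constant vector), $r = 0$, or the absence of any dynamic gene
all yield the explicit label `dynamic-unassigned` rather than a forced
group — the honest outcome for valleys the rule cannot place. Lineage
means are unweighted means over the samples of a lineage.

# Annotation and the knockout comparison

Chromatin states (K4-only / K27-only / K4+K27 / none) use any-overlap
(≥ 1 bp) with the peak sets; overlap with a Polycomb-component peak set
(e.g. EED) flags Polycomb valleys. `partition_cgi()` splits each valley
into CGI and non-CGI parts that tile it exactly — the conservation is
tested, not assumed.

`methylation_change()` computes coverage-weighted means per region in both
methylomes and $\Delta m = m_{KO} - m_{WT}$, plus pooled $\Delta m$ on the
CGI and non-CGI parts. The hypermethylation flag (threshold 0.1, a
configurable default; nothing in the valley definition fixes it) is
reported at region level *and* per part. The part-level flags matter:
CpG islands are ~10× denser in CpGs than the valley background, so in a
count-weighted mean the unchanged islands dilute a purely non-island gain
— a valley with a genuine 0.3 gain on its non-CGI part can show a
whole-region Δm well under 0.1. Hypermethylation of Polycomb valleys is
therefore assessed on the non-CGI part, where the biology places the
effect.

# Enrichment against length-matched controls

TF-site density in valleys is compared with length-matched random
controls: every valley's length is re-placed uniformly on the genome
(chromosome chosen proportional to length, optional exclusion set honoured
by rejection sampling), `n_draws` times under a fixed seed. The density
statistic is site midpoints per kb of region. The empirical p-value uses
add-one smoothing,

$$p = \frac{1 + \#\{\text{controls} \ge \text{observed}\}}{1 + n},$$

bounded below by $1/(1+n)$ and never anti-conservative; the fold is
observed density over the control mean, flagged undefined when that mean
is zero. Meta-profiles rescale each valley body to 20 bins and add fixed
20-kb flanks (20 bins each): valleys vary 8-fold in length, so body bins
must be relative while flank decay is an absolute-distance phenomenon.
The flank size and bin counts are explicit configuration, not a claim
about any particular published profile.

# Signal and expression normalization

ChIP-seq bins are normalized as RPKM,
$x_b / ((w/1000)(N/10^6))$, then genome-wide Z-scored. The Z-score uses
the *population* SD (divide by $n$), a fixed documented convention chosen
so the output has SD exactly 1; by default only covered bins enter the
statistics (`covered_only`), with a flag to count missing bins as zero
signal instead. Expression tables are quantile-normalized (rank to
column-wise mean of sorted values, ties averaged — delegated to
`limma::normalizeQuantiles`) and log2-transformed with pseudocount 1.

# What the generator emulates — and what it does not

`simulate_dmv_study()` is a first-class, tested module, not a fixture. It
plants, per seeded configuration:

* a 10-Mb two-chromosome genome (default) with geometric CpG spacing
  (mean 100 bp) and dense CGI blocks (mean 10 bp spacing, 0.5–2 kb);
* 50 valleys of 5–40 kb, aligned to the 1-kb bin grid, separated by
  ≥ 10 kb, at 70 % / 20 % / 10 % group proportions;
* background methylation Beta(8, 2) (mean 0.8), CGIs at 0.02, constant
  valleys at 0.03, dynamic valleys at per-lineage levels drawn as a random
  permutation of (0.02, 0.05, 0.08, 0.11);
* a contained tsDMR (2.5–4 kb) in every dynamic valley, plus background
  decoys (half shorter than 2 kb to exercise the strict filter);
* one gene per valley at the valley midpoint; dynamic genes peak
  (FPKM 6–20) in the lineage where the valley is least (group II) or most
  (group III) methylated, with basal lineages at 0–1.2 — satisfying the
  dynamic-gene rule by construction even after the mild log-normal sample
  noise (SD 0.05);
* observed counts: total $\sim$ Poisson(λ = 30) per site and lineage
  (zero-coverage sites dropped, creating the missing-bin cases the caller
  must handle), methylated $\sim$ Binomial(total, true level);
* a WT/KO pair in which the KO gains 0.3 on the non-CGI parts of Polycomb
  (group I) valleys only, both methylomes independently resampled;
* TF sites at 0.5/kb background and 3× that inside valleys, K4 peaks on
  dynamic-valley promoters, K27/EED peaks on Polycomb valleys,
  super-enhancers at per-group rates, and CGI scores drawn lower inside
  valleys.

Two placement rules exist purely so the truth set is well-posed for
validation: valleys snap to the 1-kb grid (the caller's resolution is the
bin grid, so off-grid 5-kb valleys can be undetectable by construction),
and background CGIs keep ≥ 6 kb from valleys *and from each other* — a
single ≤ 2 kb unmethylated island cannot pull a 5-kb window mean below
0.15, but a close pair can, which would plant a genuine valley outside the
recorded truth.

What passing tests on this generator do **not** show about real data: the
simulation has no sequence composition, no bisulfite conversion error, no
copy-number or mappability artefacts, no correlated noise between
neighbouring CpGs, no partially methylated domains, and lineage levels are
exact constants rather than mixtures of cell types. Recovery statistics
here are best-case sampling-noise results, not an error model for real
methylomes.

Every component draws from a sub-seed derived from the master seed
(`seed * 10 + k`), so adding or re-running one component never perturbs
the others, and a study is byte-identical under one configuration.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; the Bismark
  CpG-report reader merges minus-strand counts onto the plus-strand C
  (position − 1) before shifting to 0-based.
* Overlapping intervals within one input set are union-merged with a
  warning on load, because all coverage-fraction arithmetic assumes
  disjoint sets; TSS sets can opt out.
* Chromosomes present in data but absent from the genome layout are a hard
  error, never a silent skip.
* Strict inequalities are used exactly where the definitions state them:
  `< 0.15` window mean, `> 2 kb` tsDMRs, `> 0.5` coverage, `> min_len` in
  `filter_by_length()`.
* An empty valley set flows through the whole pipeline (empty
  classification, zero summaries, exit without error); a region with no
  coverage yields `NA` with a warning, and a constant track is an error in
  `zscore_track()` rather than a silent division by zero.
* `enrichment_test()` warns below 100 control draws; correlation on fewer
  than 3 lineages is an error, and a constant methylation or expression
  vector returns `NA` (undefined), which classification maps to
  `dynamic-unassigned`.

# Problem sizes

The shipped validation suite runs the caller–oracle comparison on 100
random 1-Mb tracks, planted-valley recovery and the KO analysis on the
default 10-Mb / 50-valley / λ = 30 study, classification recovery on 60
valleys, and enrichment calibration on 50 seeded 5-Mb studies with 1000
control draws each; `scripts/acceptance.R` re-runs the full pipeline at
the 10-Mb scale. These sizes give stable statistics for every check while
keeping a complete run in the low minutes on one CPU.

# Known limitations

* The caller is a thresholded window scan, matching the published valley
  definition; it is not an HMM or changepoint segmentation and makes no
  attempt at sub-kilobase boundaries.
* Group assignment relies on a four-point correlation sign; valleys whose
  dynamics are driven by genes outside them (or by multiple conflicting
  genes) land in `dynamic-unassigned` by design.
* tsDMRs and super-enhancers are inputs, not called here; BAM parsing,
  alignment and peak calling are out of scope.
* The enrichment null places control regions uniformly (optionally outside
  an exclusion set); it does not match GC content, gene density or other
  covariates.
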