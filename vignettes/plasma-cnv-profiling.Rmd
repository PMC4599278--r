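---
title: "Plasma cfDNA copy-number profiling and the PGA/TEff statistics"
author: "plasmaPGA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma cfDNA copy-number profiling and the PGA/TEff statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaPGA)
```

## The problem and the model

Plasma cell-free DNA (cfDNA) in a cancer patient is a mixture: a fraction
$f$ (the *tumor fraction*) of fragments derives from tumor cells, the rest
from normal (predominantly hematopoietic) cells. A genomic segment present
at tumor copy number $c$ is then represented in cfDNA at the relative rate

$$ r(c, f) \;=\; (1 - f) + f\,\frac{c}{2}, $$

relative to a diploid genome, so its expected log2 read-depth ratio against
a matched diploid reference is $\log_2\!\big(1 + f\,(c-2)/2\big)$
(`expected_log2_ratio()`). At the shallow sequencing depths this package
targets (roughly 14.5 million mappable reads per library, i.e. ~4,600 reads
per 1 Mb bin over a 3,113-bin male genome), individual copy-number events
are visible as shifts of bin-level read-depth ratios, and the *aggregate*
burden of such shifts is a proxy for $f$.

The pipeline is:

1. **Binning** (`tile_genome()`): hg19 chr1–22, X, Y tiled into 1 Mb
   windows, 0-based half-open, final window truncated at the chromosome
   end. This tiling yields exactly 3,113 bins; the count is only reached
   when truncated terminal bins are retained and chrY is included (the
   cohort is male), which is why those are the defaults.
2. **Counting** (`count_reads()` / `load_counts_table()`): primary, mapped,
   non-duplicate alignments with MAPQ ≥ 30, assigned to the bin containing
   the leftmost aligned base.
3. **Global-mean normalization** (`normalize_global_mean()`): each library
   is scaled to mean 1 across bins, removing library-size differences.
4. **Matched-germline ratio** (`log2_ratio()`): per bin,
   $\log_2(\text{plasma}/\text{germline})$ using the *same patient's*
   lymphocyte DNA as reference. This cancels constitutional CNVs, which
   population-reference scores (genome-wide z-scores and similar) cannot.
5. **GC correction** (`gc_correct()`): residuals of a loess (degree 1)
   fit of log2 ratio on per-bin GC fraction.
6. **Scoring** (`pga_score()`, `teff_index()`), **segmentation**
   (`segment_profile()`), **locus calls** (`call_loci()`).

## The PGA score

Let $a_1, \dots, a_n$ be the absolute GC-corrected log2 ratios (ALRs) over
usable bins and $\mathrm{ALR}.i$ their $i$-th percentile. The Plasma
Genomic Abnormality score is

$$ \mathrm{PGA} \;=\; \sum_{\,\mathrm{ALR}.95 \,\le\, a \,\le\, \mathrm{ALR}.99} a^2 . $$

ALR.95 is the minimum-abnormality threshold: with ~4% of bins in the
window, a flat (tumor-free) profile contributes only the square of its
noise quantiles, while real events push large ALRs into the window. The
top percentile is excluded because the most extreme bins in shallow-WGS
profiles are dominated by telomeric/centromeric artifacts and
low-complexity regions rather than tumor signal.

Treatment response is summarized by the Treatment Efficacy index
$\mathrm{TEff} = 10 \cdot \log_2(\mathrm{PGA}_{\text{pre}} / \mathrm{PGA}_{\text{post}})$:
zero or negative means no reduction in abnormal cfDNA burden; a doubling
of pre- over post-treatment PGA gives exactly 10. Pre-treatment scores
above 10 classify a profile as high tumor burden (`classify_pga()`,
strict inequality).

### Numerical conventions

* **Percentiles** use linear interpolation between order statistics
  (rank $r = 1 + (n-1)\,i/100$; the `quantile(type = 7)` convention). The
  window is **closed at both bounds**. Neither choice is canonical; both
  shift the score by less than one bin's contribution, and fixing them
  makes the score exactly reproducible and testable against a sort-based
  oracle.
* **Masked bins** (germline raw count < 100, zero plasma count, missing
  GC) are excluded from both the percentile computation and the sum —
  *not* treated as zeros, which would dilute ALR.95. No pseudocounts are
  used anywhere for the same reason.
* **Summation order**: the squared ALRs are accumulated in ascending
  order, so the floating-point result is independent of bin order.
* **TEff flooring**: an exactly zero PGA (possible on a flat profile) is
  floored at $10^{-6}$ with a warning, keeping the index finite and
  conservative.
* **GC correction** uses `loess(..., degree = 1, surface = "direct")`:
  the direct surface is exact (no interpolation grid), deterministic, and
  reproduces a linear GC trend to machine precision; span defaults to 0.3.
  At least 50 usable bins are required for a fit.

## Segmentation and locus calls

Profiles are segmented per chromosome by recursive binary splitting: the
candidate breakpoint maximizes the pooled-variance two-sample $t$
statistic between the two sides, and is accepted when its within-segment
permutation p-value (1,000 permutations, seeded) is below $\alpha = 0.01$.
This is the classic circular-binary-segmentation recursion; it replaces
the proprietary segmentation software used historically for such profiles.
The PGA score never depends on segmentation, so this choice does not
touch the headline statistic.

Gain/loss calls at the bundled hg19 loci (AR, PTEN, the TMPRSS2–ERG
interval, 8q) threshold the regional mean log2 ratio at ±0.2 by default.
No numeric thresholds are canonical for figure-level gain/loss statements,
so these are configuration knobs, and reports always record the values
used. Fusion-gene inference itself is out of scope; a TMPRSS2-interval
loss is reported as the sign of the interval mean.

## Somatic variants and pathway shifts

A variant is called somatic iff its cfDNA VAF is ≥ 2% **and** the matched
germline shows VAF ≤ 1% at depth ≥ 20, with cfDNA depth ≥ 50
(`call_somatic()`). The 2% cutoff alone would call constitutional SNPs;
the germline conditions are this package's defaults (recorded in every
report) because a bare cfDNA threshold is not a complete calling rule. A
gene is "mutated" if at least one called variant falls in it. Pre/post
mutated-gene sets are compared per pathway against a user-supplied GMT
collection intersected with a background universe (e.g. a 578-gene
panel); a pathway is flagged when the absolute difference in mutated-gene
counts strictly exceeds 3. No enrichment p-values are computed — the rule
is a raw count difference by design.

## What the synthetic cohort emulates — and what it does not

`simulate_pair()` draws germline bin counts from a negative binomial with
per-bin rates proportional to bin width times a multiplicative GC-bias
factor $\exp\{\beta\,(\mathrm{gc} - \overline{\mathrm{gc}})\}$; plasma
counts use the same model with each bin's rate additionally multiplied by
$r(c, f)$, and totals renormalized to the target depth (sequencer output
is fixed by the run, not by tumor burden — this induces a small global
shift of $-\log_2 \bar r$ that the global-mean normalization also sees in
real data).

Chosen conditions, fixed once:

* **Depth**: 14.5 million reads per library at hg19 scale; small synthetic
  genomes keep the *per-bin* depth (~4,600 reads) by scaling
  `total_reads = 4600 * n_bins`.
* **Noise**: shared NB size 2000, i.e. per-bin log2-ratio SD ≈ 0.055 and
  mean absolute ALR ≈ 0.044 on tumor-free pairs. This is the noise scale
  at which a 3,113-bin baseline PGA lands at a few units, so that the
  high-burden cutoff of 10 separates tumor-driven scores from noise; a
  much more dispersed generator would push flat-profile scores past the
  cutoff and make the score scale meaningless.
* **Events**: an arm-scale 30-bin gain (cn 3), a focal 8-bin deletion
  (cn 1) and a focal 10-bin amplification (cn 6) on a 300-bin, 3-chromosome
  synthetic genome — realistic spans for 8q gain, PTEN loss and AR
  amplification. Accuracy checks of event-mean recovery use a 60-bin
  event on a 2,000-bin genome (~3% of bins): when events occupy a large
  fraction of a small genome, the global-mean renormalization itself
  biases event means by more than the tolerance (a Jensen-gap effect of
  the normalization, not an estimator defect), which real genomes do not
  exhibit at this magnitude.
* **GC fractions** uniform in 0.35–0.55, germline GC slope 1 (stress tests
  use a plasma slope of 3 so the bias survives the matched ratio).

The generator does **not** emulate: fragment-length (fragmentomics)
structure, mappability variation, subclonal mixtures of events, read-level
errors, or germline CNVs (the matched-ratio step is exercised by
construction, not by simulated constitutional variants). Passing tests on
synthetic cohorts therefore validate the *computational* pipeline — not
wet-lab performance on real plasma, where artifact structure is richer.

Problem sizes in the test and acceptance suites (300–2,000 bins, 5–50
replicates, 100–1,000 permutations) were chosen so the statistical checks
have adequate power while the full suite stays fast to run routinely.

## Known limitations

* PGA compares best between profiles with similar usable-bin counts; the
  percentile window adapts to $n$, but extreme masking changes which bins
  compete for it.
* The score is a burden proxy, not a calibrated tumor-fraction estimate;
  mapping PGA to $f$ depends on the (unknown) event landscape.
* Binary segmentation tests one breakpoint at a time; perfectly symmetric
  double changes within one segment can mask each other at small effect
  sizes.
* Clinical endpoints: the package exports a survival table
  (`export_survival_table()`) for external modelling but deliberately fits
  no survival models itself.
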