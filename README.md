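# plasmaPGA

Copy-number profiling of plasma cell-free DNA (cfDNA) from shallow
whole-genome sequencing, scored for tumor burden and treatment response.

## What it does, and for whom

Advanced prostate cancer is hard to biopsy — metastases are predominantly
osseous and primary tumors are often resected — so *liquid biopsy* of plasma
cfDNA is an attractive window onto the tumor genome. This package implements
the computational side of that assay for analysts working with matched
plasma/lymphocyte sequencing:

* **1 Mb bin counting** of aligned reads over hg19 chr1–22, X, Y
  (3,113 bins), with global-mean normalization;
* **matched-germline log2 ratios** — each patient's lymphocyte DNA is the
  reference, cancelling constitutional CNVs that population references
  cannot;
* **GC-bias correction** by loess residuals;
* the **Plasma Genomic Abnormality (PGA) score**, the sum of squared
  absolute log2 ratios (ALRs) between their 95th and 99th percentiles,

  `PGA = Σ a²  for  ALR.95 ≤ a ≤ ALR.99`,

  a tumor-burden proxy in which ALR.95 acts as the minimum-abnormality
  threshold and the top percentile is excluded as artifact-prone; and the
  **Treatment Efficacy (TEff) index**,
  `TEff = 10·log2(prePGA / postPGA)`, where ≤ 0 indicates no response;
* **circular binary segmentation** (permutation-tested recursive splitting)
  and gain/loss calls at recurrent prostate-cancer loci (AR, PTEN, the
  TMPRSS2–ERG interval, 8q);
* **somatic mutation calling** from cfDNA vs germline allele fractions
  (cfDNA VAF ≥ 2%, germline-negative) and **pre/post-treatment pathway
  shifts** against GMT gene sets (flagged when mutated-gene counts differ
  by more than 3);
* a seeded **synthetic-cohort generator** (negative-binomial bin counts
  with GC bias and tumor-fraction-scaled CNV events) so every stage is
  testable without patient data.

## Worked example

Simulate one patient (tumor fraction 0.30 before treatment, 0.05 after,
with an AR amplification, a PTEN loss and an 8q gain), run the pipeline,
and score response:

```r
library(plasmaPGA)
cohort <- simulate_cohort(1, pre_f = 0.3, post_f = 0.05, seed = 1)
p <- cohort$patients$P001

pre  <- gc_correct(log2_ratio(normalize_global_mean(p$pre),
                              normalize_global_mean(p$germline)))
post <- gc_correct(log2_ratio(normalize_global_mean(p$post),
                              normalize_global_mean(p$germline)))
pre_score  <- pga_score(pre)
post_score <- pga_score(post)
print(pre_score)
print(post_score)
print(teff_index(pre_score, post_score))
```

```
PGA score: 3.1326 (patient P001, timepoint pre)
  ALR.95 = 0.2374, ALR.99 = 0.6792; 12 of 300 usable bins in window; class: low
PGA score: 0.2623 (patient P001, timepoint post)
  ALR.95 = 0.1182, ALR.99 = 0.1715; 12 of 300 usable bins in window; class: low
TEff index: 35.78 (patient P001; pre PGA 3.1326, post PGA 0.2623)
  interpretation: response (higher = better)
```

The pre-treatment score (3.13) is an order of magnitude above the
post-treatment one (0.26) — the squared-ALR window amplifies the shrinking
of copy-number shifts as tumor fraction falls — and the TEff index of +35.8
marks a strong responder. Segmentation and locus calling on the
pre-treatment profile recover the simulated events:

```r
segment_profile(pre, seed = 1)        # 30-bin gain on sim1 found at bins 51-80
ar <- default_event_catalog()[3, ]    # the simulated AR amplification
call_locus(pre, list(chrom = ar$chrom, start = ar$start, end = ar$end,
                     name = "AR_amp"))
```

```
   locus chrom start   end mean_log2 n_bins call
1 AR_amp  sim3 6e+07 7e+07 0.6584172     10 gain
```

The interval mean of 0.658 sits near the mixture-model expectation
`expected_log2_ratio(0.3, 6) = log2(1.6) ≈ 0.678` for a 6-copy
amplification at tumor fraction 0.30.

For real data, start from `read_chrom_sizes()` + `tile_genome()` (the
bundled hg19 sizes give the 3,113-bin male genome), `count_reads()` on
SAM/BAM or `load_counts_table()` on TSV counts, and `run_pipeline()` for
the end-to-end report bundle (profiles, segments, scores, TEff, somatic
calls, pathway shifts, survival table, manifest). See the methods
vignette (`vignettes/plasma-cnv-profiling.Rmd`) for the model,
conventions and limitations.

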