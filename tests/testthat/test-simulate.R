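test_that("expected log2 ratio follows the cfDNA mixture closed form", {
  expect_equal(expected_log2_ratio(0, 5), 0)
  expect_equal(expected_log2_ratio(0.3, 6), log2(1.6))
  expect_equal(expected_log2_ratio(0.2, 1), log2(0.9))
  expect_equal(expected_log2_ratio(0.5, 0), log2(0.5))
  expect_error(expected_log2_ratio(1, 4), "\\[0, 1\\)")
  expect_error(expected_log2_ratio(0.3, -1), "copy number")
})

test_that("simulated pairs are reproducible from the seed", {
  cfg <- sim_config(synthetic_bin_set(), tumor_fraction = 0.2,
                    events = default_event_catalog(),
                    total_reads = 1e6, seed = 99)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(a$germline$counts, b$germline$counts)
  expect_identical(a$plasma$counts, b$plasma$counts)
  cfg2 <- cfg; cfg2$seed <- 100
  expect_false(identical(simulate_pair(cfg2)$plasma$counts, a$plasma$counts))
})

test_that("simulated totals match the configured depth within sampling error", {
  bins <- synthetic_bin_set()
  cfg <- sim_config(bins, total_reads = 4600 * nrow(bins), seed = 5)
  pair <- simulate_pair(cfg)
  mu <- cfg$total_reads / nrow(bins)
  sd_total <- sqrt(nrow(bins) * (mu + mu^2 / cfg$dispersion))
  expect_lt(abs(pair$germline$total_reads - cfg$total_reads), 3 * sd_total)
  expect_lt(abs(pair$plasma$total_reads - cfg$total_reads), 3 * sd_total)
})

test_that("tumor-free pairs give a near-flat profile", {
  cfg <- sim_config(synthetic_bin_set(), tumor_fraction = 0,
                    total_reads = 4600 * 300, seed = 8)
  prof <- pipeline_profile(simulate_pair(cfg))
  expect_lt(mean(abs(prof$values[prof$mask])), 0.05)
})

test_that("truth tables carry the mixture-model expected ratios", {
  bins <- synthetic_bin_set()
  ev <- default_event_catalog()
  cfg <- sim_config(bins, tumor_fraction = 0.3, events = ev,
                    total_reads = 1e6, seed = 3)
  pair <- simulate_pair(cfg)
  ar <- pair$truth$cn == 6
  expect_equal(sum(ar), 10)  # the 10-bin AR-like amplification
  expect_equal(unique(pair$truth$expected_log2[ar]), expected_log2_ratio(0.3, 6))
  expect_equal(unique(pair$truth$expected_log2[pair$truth$cn == 2]), 0)
})

test_that("pipeline estimates track the closed-form truth across tumor fractions", {
  # slope of estimated event mean on expected value, AR-like event, f grid
  ev <- default_event_catalog()[3, ]  # AR_amp only, 10 bins
  est <- truth <- numeric()
  for (f in c(0.1, 0.2, 0.3, 0.4)) {
    for (r in 1:5) {
      cfg <- sim_config(synthetic_bin_set(), tumor_fraction = f, events = ev,
                        total_reads = 4600 * 300, seed = 7000 + 100 * r + round(100 * f))
      prof <- pipeline_profile(simulate_pair(cfg))
      bins <- prof$bins
      hit <- bins$chrom == ev$chrom & bins$start >= ev$start &
        bins$start < ev$end & prof$mask
      est <- c(est, mean(prof$values[hit]))
      truth <- c(truth, expected_log2_ratio(f, 6))
    }
  }
  slope <- coef(lm(est ~ truth))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("cohorts are reproducible, responder-aware, and write valid files", {
  coh <- simulate_cohort(4, pre_f = c(0.3, 0.2, 0.1, 0.05),
                         post_f = c(0.05, 0.2, 0.02, 0.05), seed = 17)
  expect_equal(length(coh$patients), 4L)
  expect_equal(coh$clinical$volume, c("high", "high", "low", "low"))
  coh2 <- simulate_cohort(4, pre_f = c(0.3, 0.2, 0.1, 0.05),
                          post_f = c(0.05, 0.2, 0.02, 0.05), seed = 17)
  expect_identical(coh$patients$P001$pre$counts, coh2$patients$P001$pre$counts)

  dir <- tempfile()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "samples.tsv")))
  samples <- read.delim(file.path(dir, "samples.tsv"))
  expect_equal(nrow(samples), 12L)  # 3 libraries per patient
  bins <- read_bin_set(file.path(dir, "bins.bed"))
  bc <- load_counts_table(file.path(dir, samples$path[1]), bins)
  expect_equal(bc$counts, coh$patients$P001$germline$counts)

  # empty cohort still writes parseable files
  dir0 <- tempfile()
  write_cohort(simulate_cohort(0, numeric(), numeric(), seed = 1), dir0)
  expect_equal(nrow(read.delim(file.path(dir0, "samples.tsv"))), 0L)
})

test_that("responders score positive TEff and non-responders center near zero", {
  teffs <- vapply(1:20, function(r) {
    coh <- simulate_cohort(1, pre_f = 0.3, post_f = 0.05, seed = 400 + r)
    p <- coh$patients$P001
    pre <- pga_score(pipeline_profile(list(plasma = p$pre, germline = p$germline)))
    post <- pga_score(pipeline_profile(list(plasma = p$post, germline = p$germline)))
    teff_index(pre, post)$teff
  }, 0)
  expect_gte(sum(teffs > 0), 18)

  null_teffs <- vapply(1:50, function(r) {
    coh <- simulate_cohort(1, pre_f = 0.1, post_f = 0.1, seed = 600 + r)
    p <- coh$patients$P001
    pre <- pga_score(pipeline_profile(list(plasma = p$pre, germline = p$germline)))
    post <- pga_score(pipeline_profile(list(plasma = p$post, germline = p$germline)))
    teff_index(pre, post)$teff
  }, 0)
  expect_lt(abs(mean(null_teffs)), 2)
})

test_that("variant simulation respects seeds and binomial tails", {
  tab <- simulate_variant_table(50, 0.1, cf_depth = 1000, g_depth = 100,
                                germline_het_sites = 10, seed = 12)
  tab2 <- simulate_variant_table(50, 0.1, cf_depth = 1000, g_depth = 100,
                                 germline_het_sites = 10, seed = 12)
  expect_identical(tab$cf_alt, tab2$cf_alt)

  # VAF 10% at depth 1000 is essentially always called
  calls <- call_somatic(tab)
  expect_gte(sum(tab$gene[tab$true_somatic] %in% calls$mutated_genes), 49)
  # het sites carry germline alt reads and are filtered out
  het <- tab$gene[!tab$true_somatic]
  expect_equal(sum(het %in% calls$mutated_genes), 0)

  # no somatic signal and no het sites: calls bounded by the binomial tail
  null_tab <- simulate_variant_table(200, 0, cf_depth = 100, seed = 13)
  null_calls <- call_somatic(null_tab)
  # P(Binom(100, 0.001) >= 2) ~ 0.005 per site -> expect ~1 of 200, allow slack
  expect_lte(length(null_calls$mutated_genes), 6)
})
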