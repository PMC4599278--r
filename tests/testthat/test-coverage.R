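test_that("read counting assigns leftmost bases to bins and applies filters", {
  sam <- write_fixture_sam()
  cs <- structure(data.frame(chrom = "c1", length = 2500000),
                  class = c("chrom_sizes", "data.frame"))
  bins <- tile_genome(cs, 1e6)
  bc <- count_reads(sam, bins, min_mapq = 30)
  # oracle: manual count of fixture records (5 bin1, 3 bin2, 1 truncated bin3;
  # low-MAPQ, duplicate and secondary records excluded)
  expect_equal(bc$counts, c(5, 3, 1))
  expect_equal(bc$total_reads, 9)
})

test_that("read counting reconciles 'chr' prefixes and rejects foreign headers", {
  sam <- write_fixture_sam()
  cs <- structure(data.frame(chrom = "chrc1", length = 2500000),
                  class = c("chrom_sizes", "data.frame"))
  bins <- tile_genome(cs, 1e6)
  expect_message(bc <- count_reads(sam, bins), "chr")
  expect_equal(bc$counts, c(5, 3, 1))

  cs2 <- structure(data.frame(chrom = "other", length = 2500000),
                   class = c("chrom_sizes", "data.frame"))
  expect_error(count_reads(sam, tile_genome(cs2, 1e6)), "no chromosome overlap")
})

test_that("count tables round-trip and are row-order independent", {
  bins <- fake_bins(5)
  bc <- bin_counts(c(10, 20, 30, 40, 50), bins, "S1", "P1", "plasma", "pre")
  p <- tempfile(fileext = ".tsv")
  write_counts_table(bc, p)
  bc2 <- load_counts_table(p, bins)
  expect_equal(bc2$counts, bc$counts)
  expect_equal(bc2$patient_id, "P1")
  expect_equal(bc2$timepoint, "pre")

  tab <- utils::read.delim(p, comment.char = "#")
  shuf <- tab[c(3, 1, 5, 2, 4), ]
  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(shuf, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(load_counts_table(p2, bins)$counts, bc$counts)

  p3 <- tempfile(fileext = ".tsv")
  utils::write.table(tab[-2, ], p3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_counts_table(p3, bins), "missing")
})

test_that("global-mean normalization has mean one and is idempotent", {
  bins <- fake_bins(3)
  bc <- bin_counts(c(2, 4, 6), bins, "S", "P")
  n1 <- normalize_global_mean(bc)
  expect_equal(n1$norm_counts, c(0.5, 1, 1.5))
  expect_lt(abs(mean(n1$norm_counts) - 1), 1e-12)
  n2 <- normalize_global_mean(n1)
  expect_equal(n2$norm_counts, n1$norm_counts)

  const <- normalize_global_mean(bin_counts(c(7, 7, 7), bins, "S", "P"))
  expect_equal(const$norm_counts, c(1, 1, 1))
  expect_error(normalize_global_mean(bin_counts(c(0, 0, 0), bins, "S", "P")),
               "all-zero")
})

test_that("log2 ratio masks unreliable bins and is antisymmetric", {
  bins <- fake_bins(4)
  pl <- normalize_global_mean(bin_counts(c(400, 200, 200, 0), bins, "S1", "P1", "plasma", "pre"))
  gl <- normalize_global_mean(bin_counts(c(200, 200, 50, 200), bins, "S0", "P1", "germline", "na"))
  prof <- log2_ratio(pl, gl, min_germline_count = 100)
  # bin 3 masked (germline raw 50 < 100), bin 4 masked (zero plasma)
  expect_equal(prof$mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(prof$values[3:4])))
  # normalized plasma = (2, 1, 1, 0), germline = ~ (1.23, 1.23, ...)
  expect_equal(prof$values[1] - prof$values[2], 1)  # ratio 2 vs 1 -> +1 apart

  gl_as_plasma <- gl; gl_as_plasma$role <- "plasma"
  pl_as_germline <- pl; pl_as_germline$role <- "germline"
  rev <- log2_ratio(gl_as_plasma, pl_as_germline, min_germline_count = 1)
  common <- prof$mask & rev$mask
  expect_equal(rev$values[common], -prof$values[common])

  glx <- normalize_global_mean(bin_counts(c(1, 1, 1, 1), bins, "SX", "OTHER", "germline"))
  expect_error(log2_ratio(pl, glx), "matched-normal")
})

test_that("identical plasma and germline give an all-zero profile", {
  bins <- fake_bins(10)
  a <- normalize_global_mean(bin_counts(101:110, bins, "S1", "P1", "plasma", "pre"))
  b <- normalize_global_mean(bin_counts(101:110, bins, "S0", "P1", "germline", "na"))
  prof <- log2_ratio(a, b)
  expect_equal(prof$values, rep(0, 10))
})

test_that("GC correction removes a linear GC trend and only shrinks the mask", {
  n <- 200
  set.seed(5)
  gc <- runif(n, 0.3, 0.6)
  bins <- fake_bins(n, gc = gc)
  v <- 2.5 * (gc - mean(gc))          # value is an exact linear function of GC
  prof <- log_ratio_profile(v, bins, patient_id = "P", timepoint = "pre")
  corr <- gc_correct(prof, span = 0.3)
  expect_lt(max(abs(corr$values[corr$mask])), 1e-6)
  expect_true(corr$gc_corrected)
  expect_true(all(which(corr$mask) %in% which(prof$mask)))

  # flat profile: correction changes nearly nothing
  flat <- log_ratio_profile(rep(0.1, n), bins)
  cflat <- gc_correct(flat)
  expect_lt(sqrt(mean(cflat$values[cflat$mask]^2)), 0.01)

  # bins with missing GC get masked
  gc2 <- gc; gc2[1:5] <- NA
  prof2 <- log_ratio_profile(v, fake_bins(n, gc = gc2))
  expect_equal(sum(gc_correct(prof2)$mask), n - 5)

  expect_error(gc_correct(fake_profile(rnorm(20)), min_bins = 50), "usable bins")
})

test_that("profiles round-trip through the TSV writer", {
  bins <- synthetic_bin_set(n_chrom = 2, bins_per_chrom = 10, seed = 2)
  v <- rnorm(20); v[3] <- NA
  prof <- log_ratio_profile(v, bins, mask = !is.na(v),
                            patient_id = "P9", timepoint = "post",
                            gc_corrected = TRUE)
  p <- tempfile(fileext = ".tsv")
  write_profile(prof, p)
  prof2 <- read_profile(p)
  expect_equal(prof2$values, prof$values, tolerance = 1e-12)
  expect_equal(prof2$mask, prof$mask)
  expect_equal(prof2$patient_id, "P9")
  expect_true(prof2$gc_corrected)
})
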