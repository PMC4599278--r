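test_that("somatic calling applies the 2% VAF rule with germline filtering", {
  rec <- data.frame(
    gene = c("A", "B", "C"), chrom = "sim1", pos = 1:3, ref = "A", alt = "T",
    cf_depth = c(100, 100, 100), cf_alt = c(3, 1, 10),
    g_depth = c(80, 80, 80), g_alt = c(0, 0, 40),
    stringsAsFactors = FALSE)
  calls <- call_somatic(rec)
  expect_equal(calls$mutated_genes, "A")   # B below 2%, C constitutional

  # zero-depth records are dropped with a warning, not an error
  rec0 <- rbind(rec, data.frame(gene = "D", chrom = "sim1", pos = 4, ref = "A",
                                alt = "T", cf_depth = 0, cf_alt = 0,
                                g_depth = 80, g_alt = 0))
  expect_warning(calls0 <- call_somatic(rec0), "zero-depth")
  expect_equal(calls0$mutated_genes, "A")
})

test_that("somatic filter equals the row-by-row predicate oracle on random records", {
  set.seed(41)
  n <- 1000
  rec <- data.frame(
    gene = sprintf("G%03d", sample.int(300, n, replace = TRUE)),
    chrom = "sim1", pos = seq_len(n), ref = "A", alt = "T",
    cf_depth = sample.int(200, n, replace = TRUE),
    g_depth = sample.int(120, n, replace = TRUE),
    stringsAsFactors = FALSE)
  rec$cf_alt <- vapply(rec$cf_depth, function(d) sample.int(d + 1, 1) - 1L, 0L)
  rec$g_alt <- vapply(rec$g_depth, function(d) sample.int(d + 1, 1) - 1L, 0L)
  calls <- suppressWarnings(call_somatic(rec))
  expect_equal(nrow(calls$calls), sum(oracle_somatic_pass(rec)))
  expect_equal(calls$calls$pos, rec$pos[oracle_somatic_pass(rec)])

  # monotonicity: a lower VAF cutoff never removes a call
  lower <- suppressWarnings(call_somatic(rec, vaf_cutoff = 0.01))
  expect_true(all(calls$calls$pos %in% lower$calls$pos))
})

test_that("VAF boundary: exactly 2% is called, below is not", {
  rec <- data.frame(gene = c("X", "Y"), chrom = "sim1", pos = 1:2,
                    ref = "A", alt = "T", cf_depth = 100, cf_alt = c(2, 1),
                    g_depth = 80, g_alt = 0, stringsAsFactors = FALSE)
  expect_equal(call_somatic(rec)$mutated_genes, "X")
})

test_that("timepoint comparison partitions the mutated-gene union", {
  cmp <- compare_timepoints(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(cmp$shared, c("B", "C"))
  expect_equal(cmp$pre_only, "A")
  expect_equal(cmp$post_only, "D")
  expect_equal(unname(cmp$counts["shared"] + cmp$counts["pre_only"]),
               unname(cmp$counts["pre_total"]))

  same <- compare_timepoints(c("A", "B"), c("B", "A"))
  expect_equal(length(same$pre_only), 0L)
  disj <- compare_timepoints("A", "B")
  expect_equal(length(disj$shared), 0L)
})

test_that("pathway shifts count mutated genes within background and flag >3", {
  genes22 <- sprintf("GNRH%02d", 1:22)
  genes10 <- sprintf("OTH%02d", 1:10)
  gmt <- write_fixture_gmt(sets = list(GNRH_SIGNALING = genes22,
                                       OTHER = genes10))
  gs <- read_gene_sets(gmt)
  # one pre-treatment and seven post-treatment mutated genes in a 22-gene
  # pathway: delta 6, flagged
  shift <- pathway_shift(genes22[1], genes22[1:7], gs)
  g <- shift[shift$pathway == "GNRH_SIGNALING", ]
  expect_equal(g$n_pre, 1)
  expect_equal(g$n_post, 7)
  expect_equal(g$delta, 6)
  expect_true(g$flagged)

  # delta exactly 3 is NOT flagged (strict > 3)
  s3 <- pathway_shift(genes22[1:2], genes22[1:5], gs)
  expect_equal(s3$delta[s3$pathway == "GNRH_SIGNALING"], 3)
  expect_false(s3$flagged[s3$pathway == "GNRH_SIGNALING"])

  # empty sets: delta 0, unflagged; symmetry in pre/post
  s0 <- pathway_shift(character(), character(), gs)
  expect_true(all(s0$delta == 0) && !any(s0$flagged))
  a <- pathway_shift(genes22[1:6], genes22[7:8], gs)
  b <- pathway_shift(genes22[7:8], genes22[1:6], gs)
  expect_equal(a$delta, b$delta)

  # genes outside the background are not counted
  bg <- genes22[1:10]
  sbg <- pathway_shift(genes22[1:15], character(), gs, background = bg)
  expect_equal(sbg$n_pre[sbg$pathway == "GNRH_SIGNALING"], 10)

  expect_error(pathway_shift("A", "B", list()), "empty")
})

test_that("variant tables round-trip and validate their columns", {
  tab <- simulate_variant_table(5, 0.1, seed = 2)
  p <- tempfile(fileext = ".tsv")
  write_variant_table(tab, p)
  tab2 <- read_variant_table(p)
  expect_equal(tab2$cf_alt, tab$cf_alt)
  expect_error(read_variant_table(write_fixture_gmt(sets = list(A = "x"))),
               "missing column")
})

test_that("VCF records surface AD/DP depths for cfDNA and germline", {
  vcf <- write_fixture_vcf()
  rec <- read_variant_vcf(vcf, cf_sample = "CF", g_sample = "GL")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$gene, c("TP53", "AR", "PTEN"))
  expect_equal(rec$cf_alt, c(3, 1, 10))
  expect_equal(rec$cf_depth, c(100, 100, 100))
  expect_equal(rec$g_alt, c(0, 0, 40))
  # the calling rule on these records keeps only TP53 (AR below 2%,
  # PTEN heterozygous in the germline)
  expect_equal(call_somatic(rec)$mutated_genes, "TP53")
})
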