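# Fixtures are built in code at test time; nothing binary is shipped.

# Minimal bin_set of n 1Mb bins on one synthetic chromosome (flat GC).
fake_bins <- function(n, gc = 0.5) {
  structure(data.frame(chrom = "sim1", start = (0:(n - 1)) * 1e6,
                       end = (1:n) * 1e6, gc = gc, stringsAsFactors = FALSE),
            bin_size = 1e6, genome_label = "", chrom_order = "sim1",
            class = c("bin_set", "data.frame"))
}

# Profile straight from a value vector (marked GC-corrected so scoring
# functions accept it without warnings).
fake_profile <- function(values, bins = fake_bins(length(values)),
                         patient_id = "P", timepoint = "pre") {
  log_ratio_profile(values, bins, patient_id = patient_id,
                    timepoint = timepoint, gc_corrected = TRUE)
}

# Tiny SAM file: one 2.5Mb chromosome, 5 reads starting in bin 1, 3 in bin 2,
# 1 in the truncated final bin, plus reads that must be excluded
# (low MAPQ, unmapped, duplicate, secondary).
write_fixture_sam <- function(path = tempfile(fileext = ".sam")) {
  rec <- function(name, flag, pos, mapq) {
    paste(name, flag, "c1", pos, mapq, "4M", "*", 0, 0, "ACGT", "IIII",
          sep = "\t")
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:2500000",
    rec("r01", 0, 100, 60), rec("r02", 0, 5000, 60), rec("r03", 0, 999000, 60),
    rec("r04", 0, 20, 60), rec("r05", 0, 999997, 60),
    rec("r06", 0, 1000001, 60), rec("r07", 0, 1500000, 60), rec("r08", 0, 1999997, 60),
    rec("r09", 0, 2400001, 60),
    rec("r10", 0, 50, 10),        # below MAPQ threshold
    rec("r12", 1024, 60, 60),     # duplicate
    rec("r13", 256, 70, 60))      # secondary
  writeLines(lines, path)
  path
}

# FASTA with known composition for GC annotation oracles.
write_fixture_fasta <- function(path = tempfile(fileext = ".fa")) {
  writeLines(c(">c1 test-chromosome", "ACGTGGGGNNNN", ">c2", "AANNGGCC"), path)
  path
}

write_fixture_gmt <- function(path = tempfile(fileext = ".gmt"), sets) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  path
}

write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=sim1,length=100000>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "CF", "GL", sep = "\t"),
    paste("sim1", 1000, ".", "A", "T", ".", "PASS", "GENE=TP53",
          "AD:DP", "97,3:100", "80,0:80", sep = "\t"),
    paste("sim1", 2000, ".", "G", "C", ".", "PASS", "GENE=AR",
          "AD:DP", "99,1:100", "80,0:80", sep = "\t"),
    paste("sim1", 3000, ".", "C", "A", ".", "PASS", "GENE=PTEN",
          "AD:DP", "90,10:100", "40,40:80", sep = "\t")),
    path)
  path
}
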