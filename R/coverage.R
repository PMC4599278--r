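#' Per-bin read counts for one sample
#'
#' Container for raw (and, after [normalize_global_mean()], normalized) per-bin
#' read counts of one sequencing library: plasma cfDNA or matched lymphocyte
#' germline DNA.
#'
#' @param counts Numeric vector of non-negative per-bin counts, aligned to
#'   `bins`.
#' @param bins The `bin_set` the counts live on.
#' @param sample_id,patient_id Sample / patient identifiers.
#' @param role `"plasma"` or `"germline"`.
#' @param timepoint `"pre"`, `"post"` or `"na"` (germline).
#' @return A `bin_counts` object.
#' @export
bin_counts <- function(counts, bins, sample_id, patient_id,
                       role = c("plasma", "germline"),
                       timepoint = c("na", "pre", "post")) {
  role <- match.arg(role)
  timepoint <- match.arg(timepoint)
  counts <- as.numeric(counts)
  if (length(counts) != nrow(bins))
    stopf("counts length (%d) != number of bins (%d)", length(counts), nrow(bins))
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and >= 0")
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 role = role, timepoint = timepoint,
                 counts = counts, norm_counts = NULL,
                 total_reads = sum(counts), bins = bins),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin_counts: %s (patient %s, %s, timepoint %s)\n",
              x$sample_id, x$patient_id, x$role, x$timepoint))
  cat(sprintf("  %d bins, %s reads, mean %.1f reads/bin%s\n",
              length(x$counts), format(x$total_reads, big.mark = ","),
              mean(x$counts),
              if (!is.null(x$norm_counts)) ", normalized" else ""))
  invisible(x)
}

#' Count aligned reads per genomic bin
#'
#' Streams a SAM/BAM file and assigns every primary, mapped, non-duplicate
#' alignment with MAPQ >= `min_mapq` to the bin containing its leftmost
#' aligned base. Chromosome names are reconciled with the bin set by
#' adding/stripping the "chr" prefix when necessary.
#'
#' @param path SAM or BAM file.
#' @param bins A `bin_set`.
#' @param min_mapq Minimum mapping quality (default 30).
#' @inheritParams bin_counts
#' @return A `bin_counts` object with integer counts.
#' @export
count_reads <- function(path, bins, min_mapq = 30,
                        sample_id = basename(path), patient_id = sample_id,
                        role = "plasma", timepoint = "na") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                              overwrite = TRUE, indexDestination = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  bin_chroms <- unique(bins$chrom)
  strip <- function(x) sub("^chr", "", x)
  prefix_mode <- if (length(intersect(names(hdr), bin_chroms))) {
    "asis"
  } else if (length(intersect(strip(names(hdr)), strip(bin_chroms)))) {
    message("reconciling chromosome names by 'chr' prefix")
    "strip"
  } else {
    stopf("no chromosome overlap between alignment header and bin set")
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = min_mapq,
    what = c("rname", "pos"))
  aln <- Rsamtools::scanBam(path, param = param)[[1]]
  chrom <- as.character(aln$rname)
  pos <- aln$pos
  if (prefix_mode == "strip") {
    key_of <- strip
  } else {
    key_of <- identity
  }
  idx <- bin_index(bins, key_of(chrom), pos - 1L, key_of)
  keep <- !is.na(idx)
  if (!any(keep)) stopf("no usable mapped reads in %s", path)
  counts <- tabulate(idx[keep], nbins = nrow(bins))
  bin_counts(counts, bins, sample_id = sample_id, patient_id = patient_id,
             role = role, timepoint = timepoint)
}

# Map (chrom key, 0-based position) to bin row index; NA when off-genome.
# `key_of` maps bin_set chromosome names into the same namespace as `chrom`.
bin_index <- function(bins, chrom, pos0, key_of = identity) {
  bin_size <- attr(bins, "bin_size")
  chroms <- attr(bins, "chrom_order") %||% unique(bins$chrom)
  offset <- c(0, cumsum(vapply(chroms, function(ch) sum(bins$chrom == ch), 0)))
  names(offset) <- c(key_of(chroms), "")
  nbin <- vapply(chroms, function(ch) sum(bins$chrom == ch), 0)
  names(nbin) <- key_of(chroms)
  off <- offset[chrom]
  nb <- nbin[chrom]
  within <- pos0 %/% bin_size
  idx <- off + within + 1L
  idx[is.na(off) | within < 0 | within >= nb] <- NA_integer_
  as.integer(idx)
}

#' Load a per-bin count table
#'
#' Reads a TSV with columns `chrom`, `start`, `end`, `count` and aligns it to
#' the bin set regardless of row order. Sample metadata is taken from the
#' file's `# key=value` comment header when present; arguments override it.
#'
#' @param path TSV path.
#' @param bins A `bin_set`.
#' @param sample_id,patient_id,role,timepoint Optional metadata overrides.
#' @return A `bin_counts` object.
#' @export
load_counts_table <- function(path, bins, sample_id = NULL, patient_id = NULL,
                              role = NULL, timepoint = NULL) {
  meta <- read_meta_header(path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(tab)))
    stopf("count table needs columns: %s", paste(need, collapse = ", "))
  key_bins <- paste(bins$chrom, bins$start)
  key_tab <- paste(tab$chrom, tab$start)
  m <- match(key_bins, key_tab)
  extra <- setdiff(key_tab, key_bins)
  if (anyNA(m) || length(extra)) {
    miss <- key_bins[is.na(m)]
    stopf("count table does not cover the bin set exactly: %d missing (e.g. %s), %d extra (e.g. %s)",
          length(miss), paste(utils::head(miss, 3), collapse = "; "),
          length(extra), paste(utils::head(extra, 3), collapse = "; "))
  }
  bin_counts(tab$count[m], bins,
             sample_id = sample_id %||% meta$sample_id %||% basename(path),
             patient_id = patient_id %||% meta$patient_id %||% "NA",
             role = role %||% meta$role %||% "plasma",
             timepoint = timepoint %||% meta$timepoint %||% "na")
}

#' Write a per-bin count table
#' @param x A `bin_counts` object.
#' @param path Output TSV path.
#' @export
write_counts_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, list(sample_id = x$sample_id, patient_id = x$patient_id,
                              role = x$role, timepoint = x$timepoint,
                              total_reads = x$total_reads))
  utils::write.table(data.frame(chrom = x$bins$chrom, start = x$bins$start,
                                end = x$bins$end, count = x$counts),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize bin counts to the sample's global mean
#'
#' Divides every bin count by the sample mean, so normalized counts average 1.
#' Idempotent.
#'
#' @param x A `bin_counts` object.
#' @return The object with `norm_counts` filled.
#' @export
normalize_global_mean <- function(x) {
  base <- x$norm_counts %||% x$counts
  m <- mean(base)
  if (m <= 0) stopf("all-zero counts for sample %s", x$sample_id)
  x$norm_counts <- base / m
  x
}

#' Log-ratio profile constructor
#'
#' Per-bin log2(plasma/germline) values with a usability mask. Normally built
#' by [log2_ratio()]; exposed so simulated or externally computed profiles can
#' enter the scoring and segmentation machinery.
#'
#' @param values Numeric per-bin log2 ratios (`NA` on masked bins).
#' @param bins A `bin_set`.
#' @param mask Logical per-bin usability vector.
#' @param patient_id,timepoint Identifiers.
#' @param gc_corrected Logical.
#' @return A `log_ratio_profile` object.
#' @export
log_ratio_profile <- function(values, bins, mask = is.finite(values),
                              patient_id = "NA", timepoint = "na",
                              gc_corrected = FALSE) {
  if (length(values) != nrow(bins)) stopf("values length != number of bins")
  values[!mask] <- NA_real_
  if (any(!is.finite(values[mask])))
    stopf("non-finite log2 ratio on a usable bin")
  structure(list(patient_id = patient_id, timepoint = timepoint,
                 values = values, mask = mask,
                 gc_corrected = gc_corrected, bins = bins),
            class = "log_ratio_profile")
}

#' @export
print.log_ratio_profile <- function(x, ...) {
  cat(sprintf("log_ratio_profile: patient %s, timepoint %s\n", x$patient_id, x$timepoint))
  cat(sprintf("  %d/%d usable bins, GC-corrected: %s\n",
              sum(x$mask), length(x$mask), x$gc_corrected))
  if (any(x$mask))
    cat(sprintf("  log2 ratio range [%.3f, %.3f], SD %.3f\n",
                min(x$values[x$mask]), max(x$values[x$mask]),
                stats::sd(x$values[x$mask])))
  invisible(x)
}

#' Per-bin log2 ratio of plasma cfDNA to matched germline
#'
#' Computes log2(plasma_norm / germline_norm) per bin from two normalized
#' count profiles of the same patient. Bins with raw germline count below
#' `min_germline_count` or zero plasma count are masked out rather than
#' zero-filled: the PGA score is percentile-based and pseudocounts would
#' inject artificial extreme ratios.
#'
#' @param plasma,germline Normalized `bin_counts` of the same patient on the
#'   same bin set.
#' @param min_germline_count Minimum raw germline reads per usable bin
#'   (default 100).
#' @return A `log_ratio_profile` (not yet GC-corrected).
#' @export
log2_ratio <- function(plasma, germline, min_germline_count = 100) {
  if (!identical(plasma$patient_id, germline$patient_id))
    stopf("matched-normal contract violated: plasma patient '%s' vs germline patient '%s'",
          plasma$patient_id, germline$patient_id)
  if (!same_bins(plasma$bins, germline$bins)) stopf("bin sets differ")
  if (is.null(plasma$norm_counts) || is.null(germline$norm_counts))
    stopf("normalize both samples first (normalize_global_mean)")
  mask <- germline$counts >= min_germline_count & plasma$counts > 0
  values <- rep(NA_real_, length(mask))
  values[mask] <- log2(plasma$norm_counts[mask] / germline$norm_counts[mask])
  log_ratio_profile(values, plasma$bins, mask = mask,
                    patient_id = plasma$patient_id,
                    timepoint = plasma$timepoint, gc_corrected = FALSE)
}

#' GC-bias correction of a log-ratio profile
#'
#' Replaces the log2 ratios by the residuals of a local weighted linear
#' regression (loess, degree 1) of log2 ratio on per-bin GC fraction over
#' usable bins. Bins with missing GC are masked; the usable set only shrinks.
#'
#' @param profile A `log_ratio_profile` whose bins carry GC fractions.
#' @param span Loess span (default 0.3).
#' @param min_bins Minimum usable bins required for a stable fit (default 50).
#' @return The corrected profile (`gc_corrected = TRUE`).
#' @export
gc_correct <- function(profile, span = 0.3, min_bins = 50) {
  gc <- profile$bins$gc
  usable <- profile$mask & !is.na(gc)
  if (sum(usable) < min_bins)
    stopf("only %d usable bins with GC; need >= %d for a stable fit",
          sum(usable), min_bins)
  df <- data.frame(v = profile$values[usable], gc = gc[usable])
  fit <- stats::loess(v ~ gc, data = df, span = span, degree = 1,
                      family = "gaussian", surface = "direct")
  values <- rep(NA_real_, length(profile$values))
  values[usable] <- df$v - stats::predict(fit, newdata = df)
  log_ratio_profile(values, profile$bins, mask = usable,
                    patient_id = profile$patient_id,
                    timepoint = profile$timepoint, gc_corrected = TRUE)
}

#' Write a log-ratio profile as TSV
#' @param profile A `log_ratio_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, list(patient_id = profile$patient_id,
                              timepoint = profile$timepoint,
                              gc_corrected = profile$gc_corrected))
  utils::write.table(data.frame(chrom = profile$bins$chrom,
                                start = profile$bins$start,
                                end = profile$bins$end,
                                log2ratio = profile$values,
                                usable = profile$mask),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log-ratio profile written by [write_profile()]
#' @param path TSV path.
#' @param bins Optional `bin_set`; reconstructed from the file when omitted.
#' @export
read_profile <- function(path, bins = NULL) {
  meta <- read_meta_header(path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(bins)) {
    bins <- structure(data.frame(chrom = tab$chrom, start = tab$start,
                                 end = tab$end, gc = NA_real_,
                                 stringsAsFactors = FALSE),
                      bin_size = max(tab$end - tab$start),
                      genome_label = "", chrom_order = unique(tab$chrom),
                      class = c("bin_set", "data.frame"))
  }
  log_ratio_profile(tab$log2ratio, bins, mask = tab$usable,
                    patient_id = meta$patient_id %||% "NA",
                    timepoint = meta$timepoint %||% "na",
                    gc_corrected = identical(meta$gc_corrected, "TRUE"))
}

#' Genome-wide profile plot
#'
#' Scatter of per-bin GC-adjusted log2 ratios along the genome, optionally
#' overlaid with segment means (the classic copy-number "skyline" view).
#'
#' @param x A `log_ratio_profile`.
#' @param segments Optional segment table from [segment_profile()].
#' @param ... Passed to [graphics::plot()].
#' @method plot log_ratio_profile
#' @export
plot.log_ratio_profile <- function(x, segments = NULL, ...) {
  idx <- seq_along(x$values)
  chroms <- attr(x$bins, "chrom_order") %||% unique(x$bins$chrom)
  col <- (match(x$bins$chrom, chroms) %% 2) + 1
  graphics::plot(idx, x$values, pch = 16, cex = 0.4,
                 col = c("grey40", "grey70")[col],
                 xlab = "genomic bin", ylab = "log2 ratio (cfDNA / germline)",
                 main = sprintf("patient %s (%s)", x$patient_id, x$timepoint), ...)
  graphics::abline(h = 0, col = "steelblue", lty = 2)
  if (!is.null(segments)) {
    graphics::segments(segments$start_bin, segments$mean_log2,
                       segments$end_bin, segments$mean_log2,
                       col = "red", lwd = 2)
  }
  invisible(x)
}
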