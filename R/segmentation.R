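#' Circular binary segmentation of a log-ratio profile
#'
#' Partitions the usable bins of each chromosome into runs of constant mean
#' log2 ratio by recursive binary splitting: within a segment the candidate
#' breakpoint maximizing the standardized mean difference (two-sample t
#' statistic with pooled variance) between the two sides is accepted when its
#' permutation p-value falls below `alpha`, then both sides are split
#' recursively. Deterministic given `seed`.
#'
#' @param profile A `log_ratio_profile`.
#' @param alpha Significance level for accepting a breakpoint (default 0.01).
#' @param n_perm Number of within-segment permutations (default 1000).
#' @param seed RNG seed for the permutation tests (default 1).
#' @param min_width Minimum bins on each side of a split (default 2).
#' @return A data frame of class `cbs_segments`: `chrom`, `start_bin`,
#'   `end_bin` (1-based inclusive row indices into the profile's bin set),
#'   `start`, `end` (bp), `n_bins`, `mean_log2`. Segments partition the
#'   usable bins of each chromosome.
#' @export
segment_profile <- function(profile, alpha = 0.01, n_perm = 1000, seed = 1,
                            min_width = 2) {
  bins <- profile$bins
  chroms <- attr(bins, "chrom_order") %||% unique(bins$chrom)
  out <- list()
  with_seed(seed, {
    for (ch in chroms) {
      idx <- which(bins$chrom == ch & profile$mask)
      if (length(idx) == 0L) next
      x <- profile$values[idx]
      bounds <- split_segment(x, alpha, n_perm, min_width)
      for (b in bounds) {
        gi <- idx[b[1]:b[2]]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start_bin = gi[1], end_bin = gi[length(gi)],
          start = bins$start[gi[1]], end = bins$end[gi[length(gi)]],
          n_bins = length(gi), mean_log2 = mean(x[b[1]:b[2]]),
          stringsAsFactors = FALSE)
      }
    }
  })
  segs <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_bin = integer(), end_bin = integer(),
               start = numeric(), end = numeric(), n_bins = integer(),
               mean_log2 = numeric())
  rownames(segs) <- NULL
  class(segs) <- c("cbs_segments", "data.frame")
  segs
}

# Recursively split x; returns a list of c(first, last) index pairs (local).
split_segment <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < 2 * min_width || stats::var(x) < 1e-14) return(list(c(1L, n)))
  obs <- max_t_scan(x, min_width)
  if (!is.finite(obs$stat) && obs$stat != Inf) return(list(c(1L, n)))
  exceed <- 0L
  for (p in seq_len(n_perm)) {
    if (max_t_scan(sample(x), min_width)$stat >= obs$stat) exceed <- exceed + 1L
  }
  pval <- (exceed + 1) / (n_perm + 1)
  if (pval >= alpha) return(list(c(1L, n)))
  k <- obs$k
  left <- split_segment(x[1:k], alpha, n_perm, min_width)
  right <- split_segment(x[(k + 1):n], alpha, n_perm, min_width)
  c(left, lapply(right, function(b) b + k))
}

# Best split of x by pooled-variance t statistic, vectorized over split points.
max_t_scan <- function(x, min_width = 2) {
  n <- length(x)
  ks <- min_width:(n - min_width)
  S <- cumsum(x)
  SS <- sum(x^2)
  mL <- S[ks] / ks
  mR <- (S[n] - S[ks]) / (n - ks)
  pooled_ss <- SS - ks * mL^2 - (n - ks) * mR^2
  s2 <- pooled_ss / pmax(n - 2, 1)
  se <- sqrt(pmax(s2, 0) * (1 / ks + 1 / (n - ks)))
  d <- abs(mL - mR)
  stat <- ifelse(se > 0, d / se, ifelse(d > 0, Inf, 0))
  i <- which.max(stat)
  list(k = ks[i], stat = stat[i])
}

#' Gain/loss call at a named genomic locus
#'
#' Averages the usable bin values (or overlapping segment means, weighted by
#' bins of overlap) over a genomic region and thresholds the mean: gain when
#' `mean_log2 >= gain_threshold`, loss when `<= loss_threshold`, else neutral.
#'
#' @param profile A `log_ratio_profile`.
#' @param region A list/row with `chrom`, `start`, `end` (bp, 0-based
#'   half-open) and optionally `name`.
#' @param gain_threshold,loss_threshold log2-ratio thresholds (defaults
#'   +0.2 / -0.2; the numeric cutoffs are conventions, configurable).
#' @param segments Optional `cbs_segments`; when supplied the call uses
#'   segment means instead of raw bins.
#' @return A one-row data frame: `locus`, `chrom`, `start`, `end`,
#'   `mean_log2`, `n_bins`, `call`.
#' @export
call_locus <- function(profile, region, gain_threshold = 0.2,
                       loss_threshold = -0.2, segments = NULL) {
  stopifnot(gain_threshold > loss_threshold)
  bins <- profile$bins
  ov <- which(bins$chrom == region$chrom &
                bins$start < region$end & bins$end > region$start &
                profile$mask)
  if (length(ov) == 0L)
    stopf("no usable bins overlap locus %s (%s:%s-%s)",
          region$name %||% "?", region$chrom, region$start, region$end)
  if (is.null(segments)) {
    m <- mean(profile$values[ov])
  } else {
    so <- segments[segments$chrom == region$chrom &
                     segments$start_bin <= max(ov) &
                     segments$end_bin >= min(ov), , drop = FALSE]
    if (nrow(so) == 0L)
      stopf("no segments overlap locus %s", region$name %||% "?")
    w <- pmin(so$end_bin, max(ov)) - pmax(so$start_bin, min(ov)) + 1
    m <- sum(so$mean_log2 * w) / sum(w)
  }
  call <- if (m >= gain_threshold) "gain" else if (m <= loss_threshold) "loss" else "neutral"
  data.frame(locus = region$name %||% NA_character_,
             chrom = region$chrom, start = region$start, end = region$end,
             mean_log2 = m, n_bins = length(ov), call = call,
             stringsAsFactors = FALSE)
}

#' Call gains and losses over a locus catalog
#'
#' @param profile A `log_ratio_profile`.
#' @param catalog A data frame with columns `chrom`, `start`, `end`, `name`
#'   (e.g. from [read_locus_bed()] or [default_locus_catalog()]).
#' @inheritParams call_locus
#' @return A data frame with one row per callable locus; loci without usable
#'   bins are skipped with a warning.
#' @export
call_loci <- function(profile, catalog = default_locus_catalog(),
                      gain_threshold = 0.2, loss_threshold = -0.2,
                      segments = NULL) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    tryCatch(call_locus(profile, as.list(catalog[i, ]), gain_threshold,
                        loss_threshold, segments),
             error = function(e) {
               warning(conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  do.call(rbind, rows)
}

#' Read a locus catalog from a BED file
#'
#' @param path BED file (chrom, start, end, name).
#' @return Data frame with columns `chrom`, `start`, `end`, `name`
#'   (0-based half-open coordinates, as in BED).
#' @export
read_locus_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = gr$name,
             stringsAsFactors = FALSE)
}

#' Default hg19 locus catalog (AR, PTEN, TMPRSS2-ERG, 8q)
#'
#' The recurrently aberrant prostate-cancer loci shipped with the package:
#' AR amplification (chrX), PTEN deletion (chr10), the TMPRSS2-ERG interval
#' (chr21; a genomic loss over the interval accompanies the fusion), and the
#' 8q arm gain.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
default_locus_catalog <- function() {
  read_locus_bed(system.file("extdata", "loci_hg19.bed", package = "plasmaPGA"))
}

#' Write segments as TSV
#' @param segments A `cbs_segments` data frame.
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, list())
  utils::write.table(as.data.frame(segments), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
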