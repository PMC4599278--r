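#' Percentile of absolute log2 ratios (ALR)
#'
#' The i-th percentile of the absolute log2 ratios over usable bins, with the
#' linear-interpolation convention: on the sorted values the rank is
#' r = 1 + (n-1) * i/100, interpolating between adjacent order statistics
#' (the same convention as `quantile(type = 7)`).
#'
#' @param profile A `log_ratio_profile`.
#' @param i Percentile in \[0, 100\].
#' @return The ALR.i value.
#' @export
alr_percentile <- function(profile, i) {
  a <- abs(profile$values[profile$mask])
  if (length(a) < 1L) stopf("no usable bins")
  if (!is.numeric(i) || i < 0 || i > 100) stopf("percentile i must be in [0, 100]")
  interp_percentile(sort(a), i)
}

# rank-interpolated percentile on an already-sorted vector
interp_percentile <- function(s, i) {
  n <- length(s)
  if (n == 1L) return(s)
  h <- 1 + (n - 1) * i / 100
  lo <- floor(h)
  frac <- h - lo
  if (lo >= n) return(s[n])
  s[lo] + frac * (s[lo + 1] - s[lo])
}

#' Plasma Genomic Abnormality (PGA) score
#'
#' Tumor-burden statistic for a GC-corrected cfDNA/germline log2-ratio
#' profile: the sum of squared absolute log2 ratios (ALRs) lying between the
#' 95th and 99th ALR percentiles, both bounds inclusive. ALR.95 acts as the
#' minimum abnormality threshold; the top one percentile is excluded because
#' extreme bins are dominated by telomeric/centromeric artifacts rather than
#' tumor signal. A higher score indicates a greater tumor DNA fraction in the
#' cfDNA.
#'
#' @param profile A `log_ratio_profile` (GC-corrected; a warning is issued
#'   otherwise).
#' @param min_bins Minimum usable bins required (default 100).
#' @param lower,upper Percentile window bounds (defaults 95 and 99).
#' @return A `pga_result` with fields `pga`, `alr95`, `alr99`, `n_bins_used`,
#'   `n_bins_in_window`.
#' @export
pga_score <- function(profile, min_bins = 100, lower = 95, upper = 99) {
  if (!isTRUE(profile$gc_corrected))
    warning("profile is not GC-corrected; PGA scores are intended for corrected profiles",
            call. = FALSE)
  a <- abs(profile$values[profile$mask])
  if (length(a) < min_bins)
    stopf("only %d usable bins; need >= %d", length(a), min_bins)
  s <- sort(a)
  alr_lo <- interp_percentile(s, lower)
  alr_hi <- interp_percentile(s, upper)
  sel <- s[s >= alr_lo & s <= alr_hi]   # ascending order: summation is reproducible
  structure(list(patient_id = profile$patient_id,
                 timepoint = profile$timepoint,
                 pga = sum(sel^2),
                 alr95 = alr_lo, alr99 = alr_hi,
                 n_bins_used = length(a),
                 n_bins_in_window = length(sel)),
            class = "pga_result")
}

#' @export
print.pga_result <- function(x, ...) {
  cat(sprintf("PGA score: %.4f (patient %s, timepoint %s)\n",
              x$pga, x$patient_id, x$timepoint))
  cat(sprintf("  ALR.95 = %.4f, ALR.99 = %.4f; %d of %d usable bins in window; class: %s\n",
              x$alr95, x$alr99, x$n_bins_in_window, x$n_bins_used,
              classify_pga(x)))
  invisible(x)
}

#' Treatment Efficacy (TEff) index
#'
#' Quantifies treatment response from the pre/post-treatment PGA scores of
#' one patient: TEff = log2(prePGA / postPGA) * 10. Values at or near zero
#' indicate no response; larger values indicate greater reduction of the
#' abnormal cfDNA fraction. Zero scores are floored at `eps` (with a warning)
#' to keep the index finite.
#'
#' @param pre,post `pga_result` objects (or bare non-negative numbers) for the
#'   same patient.
#' @param eps Floor applied to zero/near-zero PGA values (default 1e-6).
#' @return A `teff_result` with fields `pre_pga`, `post_pga`, `teff`.
#' @export
teff_index <- function(pre, post, eps = 1e-6) {
  pid <- NA_character_
  if (inherits(pre, "pga_result") && inherits(post, "pga_result")) {
    if (!identical(pre$patient_id, post$patient_id))
      stopf("mismatched patients: '%s' vs '%s'", pre$patient_id, post$patient_id)
    pid <- pre$patient_id
  }
  p1 <- if (inherits(pre, "pga_result")) pre$pga else as.numeric(pre)
  p2 <- if (inherits(post, "pga_result")) post$pga else as.numeric(post)
  if (p1 < eps || p2 < eps) {
    warning(sprintf("PGA value below %g floored for TEff computation", eps),
            call. = FALSE)
    p1 <- max(p1, eps)
    p2 <- max(p2, eps)
  }
  structure(list(patient_id = pid, pre_pga = p1, post_pga = p2,
                 teff = log2(p1 / p2) * 10),
            class = "teff_result")
}

#' @export
print.teff_result <- function(x, ...) {
  cat(sprintf("TEff index: %.2f (patient %s; pre PGA %.4f, post PGA %.4f)\n",
              x$teff, x$patient_id, x$pre_pga, x$post_pga))
  cat(sprintf("  interpretation: %s\n",
              if (x$teff <= 0) "no response" else "response (higher = better)"))
  invisible(x)
}

#' Classify a PGA score as high or low tumor burden
#'
#' `"high"` iff the score strictly exceeds the cutoff (default 10, the
#' high/low-volume disease threshold).
#'
#' @param result A `pga_result` or a bare number.
#' @param cutoff Strict threshold (default 10).
#' @return `"high"` or `"low"`.
#' @export
classify_pga <- function(result, cutoff = 10) {
  pga <- if (inherits(result, "pga_result")) result$pga else as.numeric(result)
  if (pga > cutoff) "high" else "low"
}

#' One-row data frame view of a PGA result
#' @param x A `pga_result`.
#' @param ... Unused.
#' @method as.data.frame pga_result
#' @export
as.data.frame.pga_result <- function(x, ...) {
  data.frame(patient_id = x$patient_id, timepoint = x$timepoint,
             pga = x$pga, alr95 = x$alr95, alr99 = x$alr99,
             n_bins_used = x$n_bins_used,
             n_bins_in_window = x$n_bins_in_window,
             classification = classify_pga(x),
             stringsAsFactors = FALSE)
}
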