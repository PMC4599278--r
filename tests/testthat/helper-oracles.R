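# Independent oracles, kept deliberately separate from the implementation
# code paths they check.

# Sort-based PGA oracle: quantile(type = 7) bounds, inclusive window,
# sum of squares accumulated in ascending order.
oracle_pga <- function(values, lower = 95, upper = 99) {
  a <- sort(abs(values[is.finite(values)]))
  q <- stats::quantile(a, probs = c(lower, upper) / 100, type = 7, names = FALSE)
  sel <- a[a >= q[1] & a <= q[2]]
  sum(sel^2)
}

# Exhaustive split-scan segmentation oracle for noiseless profiles:
# recursively place the breakpoint maximizing |mean difference|.
oracle_breakpoints <- function(x, tol = 1e-12) {
  n <- length(x)
  if (n < 2 || max(x) - min(x) < tol) return(integer())
  ks <- seq_len(n - 1)
  d <- abs(cumsum(x)[ks] / ks - (sum(x) - cumsum(x)[ks]) / (n - ks))
  k <- which.max(d)
  if (d[k] < tol) return(integer())
  sort(c(oracle_breakpoints(x[1:k]), k, k + oracle_breakpoints(x[(k + 1):n])))
}

# Row-by-row somatic filter predicate.
oracle_somatic_pass <- function(rec, vaf_cutoff = 0.02, min_cf_depth = 50,
                                max_germline_vaf = 0.01, min_g_depth = 20) {
  ok <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    if (r$cf_depth == 0 || r$g_depth == 0) { ok[i] <- FALSE; next }
    ok[i] <- (r$cf_alt / r$cf_depth >= vaf_cutoff) &&
      (r$cf_depth >= min_cf_depth) &&
      (r$g_depth >= min_g_depth) &&
      (r$g_alt / r$g_depth <= max_germline_vaf)
  }
  ok
}

# Run the coverage pipeline on a simulated pair and return the GC-corrected
# profile (shared by several simulation-based checks).
pipeline_profile <- function(pair, min_germline_count = 100, span = 0.3) {
  gc_correct(log2_ratio(normalize_global_mean(pair$plasma),
                        normalize_global_mean(pair$germline),
                        min_germline_count = min_germline_count),
             span = span)
}
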