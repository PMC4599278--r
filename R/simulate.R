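#' Expected log2 ratio of a copy-number event in cfDNA
#'
#' Under the two-component mixture view of plasma cfDNA (tumor fraction `f`
#' of fragments from a tumor at copy number `cn`, the rest from diploid
#' normal cells), the relative representation of a bin is
#' (1 - f) + f * cn / 2, so its expected log2 ratio against the matched
#' germline is `log2(1 + f * (cn - 2) / 2)`.
#'
#' @param f Tumor fraction in \[0, 1).
#' @param cn Integer tumor copy number (diploid background = 2).
#' @return Expected log2 ratio.
#' @examples
#' expected_log2_ratio(0.3, 6)  # log2(1.6) ~= 0.678
#' expected_log2_ratio(0.2, 1)  # log2(0.9) ~= -0.152
#' @export
expected_log2_ratio <- function(f, cn) {
  if (any(f < 0 | f >= 1)) stopf("tumor fraction must be in [0, 1)")
  if (any(cn < 0)) stopf("copy number must be >= 0")
  rel <- 1 + f * (cn - 2) / 2
  if (any(rel <= 0)) stopf("nonpositive relative copy: f*(cn-2)/2 <= -1")
  log2(rel)
}

#' Copy-number event descriptor
#'
#' @param chrom,start,end Event region (bp, 0-based half-open).
#' @param cn Integer tumor copy number (must differ from 2).
#' @param label Event label, e.g. `"AR_amp"`.
#' @return A one-row data frame.
#' @export
cnv_event <- function(chrom, start, end, cn, label) {
  if (cn == 2) stopf("a CNV event must have copy number != 2")
  data.frame(chrom = chrom, start = start, end = end, cn = as.integer(cn),
             label = label, stringsAsFactors = FALSE)
}

#' Synthetic bin set for simulation and testing
#'
#' A small artificial genome (default 3 chromosomes x 100 bins of 1 Mb) with
#' seeded per-bin GC fractions drawn uniformly from a human-like range
#' (0.35-0.55).
#'
#' @param n_chrom Number of chromosomes.
#' @param bins_per_chrom Bins per chromosome.
#' @param bin_size Bin width in bp.
#' @param seed Seed for the GC draw.
#' @return A `bin_set` with GC annotated.
#' @export
synthetic_bin_set <- function(n_chrom = 3, bins_per_chrom = 100,
                              bin_size = 1e6, seed = 42) {
  sizes <- structure(data.frame(chrom = paste0("sim", seq_len(n_chrom)),
                                length = bins_per_chrom * bin_size,
                                stringsAsFactors = FALSE),
                     class = c("chrom_sizes", "data.frame"))
  bins <- tile_genome(sizes, bin_size, genome_label = "synthetic")
  bins$gc <- with_seed(seed, stats::runif(nrow(bins), 0.35, 0.55))
  bins
}

#' Default simulated event catalog (AR amp, PTEN loss, 8q gain)
#'
#' The three recurrent prostate-cancer aberrations placed on the synthetic
#' genome from [synthetic_bin_set()]: an 8q-arm-like 30-bin gain (cn 3), a
#' focal 8-bin PTEN-like loss (cn 1), and a focal 10-bin AR-like
#' amplification (cn 6).
#'
#' @param bin_size Bin width used by the target bin set.
#' @return Data frame of events ([cnv_event()] rows).
#' @export
default_event_catalog <- function(bin_size = 1e6) {
  rbind(cnv_event("sim1", 50 * bin_size, 80 * bin_size, 3L, "8q_gain"),
        cnv_event("sim2", 40 * bin_size, 48 * bin_size, 1L, "PTEN_loss"),
        cnv_event("sim3", 60 * bin_size, 70 * bin_size, 6L, "AR_amp"))
}

#' Simulation configuration
#'
#' @param bins A `bin_set` (GC-annotated).
#' @param tumor_fraction Tumor fraction f in \[0, 1).
#' @param events Event catalog (data frame of [cnv_event()] rows), or NULL.
#' @param total_reads Mean total mappable reads per sample (default
#'   14,500,000, the cohort's per-sample scale; scale it with the bin count
#'   to hold per-bin depth at ~4,600 reads when simulating small genomes).
#' @param gc_bias_coeff Log-linear slope of the per-bin rate on (gc - mean
#'   gc); default 1.
#' @param plasma_gc_bias_coeff GC slope for the plasma library; defaults to
#'   the germline slope (set differently to stress-test GC correction).
#' @param dispersion Negative-binomial size parameter shared across bins
#'   (default 2000; larger = less overdispersion; the default gives per-bin
#'   log2-ratio noise of SD ~0.055 at ~4,600 reads/bin, the scale at which
#'   tumor-free profiles stay within mean absolute log2 ratio < 0.05).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(bins, tumor_fraction = 0, events = NULL,
                       total_reads = 14.5e6, gc_bias_coeff = 1,
                       plasma_gc_bias_coeff = gc_bias_coeff,
                       dispersion = 2000, seed = 1) {
  if (tumor_fraction < 0 || tumor_fraction >= 1) stopf("tumor_fraction must be in [0, 1)")
  if (dispersion <= 0) stopf("dispersion must be > 0")
  if (any(is.na(bins$gc))) stopf("bin set must be GC-annotated")
  structure(list(bins = bins, tumor_fraction = tumor_fraction,
                 events = events, total_reads = total_reads,
                 gc_bias_coeff = gc_bias_coeff,
                 plasma_gc_bias_coeff = plasma_gc_bias_coeff,
                 dispersion = dispersion, seed = seed),
            class = "sim_config")
}

# Per-bin tumor copy number implied by an event catalog (2 = neutral)
event_cn_per_bin <- function(bins, events) {
  cn <- rep(2L, nrow(bins))
  if (is.null(events) || nrow(events) == 0L) return(cn)
  for (i in seq_len(nrow(events))) {
    hit <- bins$chrom == events$chrom[i] &
      bins$start < events$end[i] & bins$end > events$start[i]
    cn[hit] <- events$cn[i]
  }
  cn
}

#' Simulate a matched germline/plasma pair of bin-count profiles
#'
#' Germline counts are negative-binomial draws around per-bin rates
#' proportional to bin width times a multiplicative GC-bias factor
#' `exp(gc_bias_coeff * (gc - mean(gc)))`. Plasma counts follow the same
#' model with each bin's rate additionally multiplied by its relative copy
#' `(1 - f) + f * cn / 2`; rates are renormalized so both libraries target
#' `total_reads` (sequencing depth is fixed by the run, not by tumor
#' burden). Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @param patient_id,timepoint Metadata for the generated samples.
#' @return A list: `germline` and `plasma` (`bin_counts`) and `truth`, a per-
#'   bin data frame with the true copy number and expected log2 ratio.
#' @export
simulate_pair <- function(config, patient_id = "SIM", timepoint = "pre") {
  bins <- config$bins
  f <- config$tumor_fraction
  cn <- event_cn_per_bin(bins, config$events)
  w <- (bins$end - bins$start) / mean(bins$end - bins$start)
  gcc <- bins$gc - mean(bins$gc)
  rate_g <- w * exp(config$gc_bias_coeff * gcc)
  rel <- (1 - f) + f * cn / 2
  rate_p <- w * exp(config$plasma_gc_bias_coeff * gcc) * rel
  mu_g <- config$total_reads * rate_g / sum(rate_g)
  mu_p <- config$total_reads * rate_p / sum(rate_p)
  counts <- with_seed(config$seed, {
    g <- stats::rnbinom(length(mu_g), mu = mu_g, size = config$dispersion)
    p <- stats::rnbinom(length(mu_p), mu = mu_p, size = config$dispersion)
    list(g = g, p = p)
  })
  germline <- bin_counts(counts$g, bins, sample_id = paste0(patient_id, "_germline"),
                         patient_id = patient_id, role = "germline", timepoint = "na")
  plasma <- bin_counts(counts$p, bins, sample_id = paste0(patient_id, "_plasma_", timepoint),
                       patient_id = patient_id, role = "plasma", timepoint = timepoint)
  truth <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                      cn = cn, expected_log2 = log2(rel), stringsAsFactors = FALSE)
  list(germline = germline, plasma = plasma, truth = truth)
}

#' Simulate a pre/post-treatment cohort
#'
#' Per patient: one germline library plus pre- and post-treatment plasma
#' libraries sharing the event catalog, with per-timepoint tumor fractions.
#' Responders are patients whose post-treatment fraction is lower than the
#' pre-treatment one. A clinical sheet (group, volume label, vital status,
#' follow-up) emulating a two-cohort advanced prostate cancer design is
#' generated alongside.
#'
#' @param n_patients Number of patients.
#' @param pre_f,post_f Numeric vectors (length `n_patients`) of tumor
#'   fractions.
#' @param events Event catalog shared by all patients.
#' @param bins A GC-annotated `bin_set` (default [synthetic_bin_set()]).
#' @param seed Cohort seed; patient seeds are derived from it.
#' @param total_reads,gc_bias_coeff,dispersion Passed to [sim_config()].
#' @param groups Optional character vector of treatment groups per patient
#'   (default: first half `"HSPC"`, rest `"CRPC"`).
#' @return A `sim_cohort` list: `patients` (per-patient list of germline /
#'   pre / post `bin_counts` and truth tables), `clinical` (data frame), and
#'   the generating parameters.
#' @export
simulate_cohort <- function(n_patients, pre_f, post_f,
                            events = default_event_catalog(),
                            bins = synthetic_bin_set(), seed = 1,
                            total_reads = 4600 * nrow(bins),
                            gc_bias_coeff = 1, dispersion = 2000,
                            groups = NULL) {
  stopifnot(length(pre_f) == n_patients, length(post_f) == n_patients)
  groups <- groups %||% rep(c("HSPC", "CRPC"), length.out = max(n_patients, 1L))[seq_len(n_patients)]
  patients <- list()
  clinical <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    cfg_pre <- sim_config(bins, tumor_fraction = pre_f[i], events = events,
                          total_reads = total_reads, gc_bias_coeff = gc_bias_coeff,
                          dispersion = dispersion, seed = seed + 1000L + i)
    cfg_post <- sim_config(bins, tumor_fraction = post_f[i], events = events,
                           total_reads = total_reads, gc_bias_coeff = gc_bias_coeff,
                           dispersion = dispersion, seed = seed + 2000L + i)
    pre <- simulate_pair(cfg_pre, patient_id = pid, timepoint = "pre")
    post <- simulate_pair(cfg_post, patient_id = pid, timepoint = "post")
    patients[[pid]] <- list(germline = pre$germline, pre = pre$plasma,
                            post = post$plasma, truth_pre = pre$truth,
                            truth_post = post$truth)
    clin <- with_seed(seed + 3000L + i, {
      dead <- stats::rbinom(1, 1, min(0.85, 0.15 + 1.8 * pre_f[i]))
      fup <- round(stats::rgamma(1, shape = 4, scale = 12 / (1 + 4 * pre_f[i])), 1)
      c(dead = dead, fup = fup)
    })
    clinical[[i]] <- data.frame(
      patient_id = pid, group = groups[i],
      volume = if (pre_f[i] >= 0.15) "high" else "low",
      pre_f = pre_f[i], post_f = post_f[i],
      vital_status = clin[["dead"]], followup_months = clin[["fup"]],
      stringsAsFactors = FALSE)
  }
  structure(list(patients = patients,
                 clinical = if (n_patients > 0) do.call(rbind, clinical) else
                   data.frame(patient_id = character(), group = character(),
                              volume = character(), pre_f = numeric(),
                              post_f = numeric(), vital_status = integer(),
                              followup_months = numeric()),
                 bins = bins, events = events, seed = seed),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk in the pipeline's input layout
#'
#' Produces the same plain-text files the pipeline reads: `chrom.sizes`,
#' `bins.bed`, per-sample count TSVs under `counts/`, a `samples.tsv`
#' manifest and `clinical.tsv`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "counts"), recursive = TRUE, showWarnings = FALSE)
  bins <- cohort$bins
  chroms <- attr(bins, "chrom_order")
  sizes <- vapply(chroms, function(ch) max(bins$end[bins$chrom == ch]), 0)
  writeLines(paste(chroms, format(sizes, scientific = FALSE, trim = TRUE), sep = "\t"),
             file.path(dir, "chrom.sizes"))
  write_bin_set(bins, file.path(dir, "bins.bed"))
  rows <- list()
  for (pid in names(cohort$patients)) {
    p <- cohort$patients[[pid]]
    for (slot in c("germline", "pre", "post")) {
      x <- p[[slot]]
      fn <- file.path("counts", paste0(x$sample_id, ".tsv"))
      write_counts_table(x, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = x$sample_id, patient_id = x$patient_id,
        role = x$role, timepoint = x$timepoint, path = fn,
        stringsAsFactors = FALSE)
    }
  }
  samples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), patient_id = character(),
               role = character(), timepoint = character(), path = character())
  utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a targeted-panel variant table
#'
#' Somatic sites draw cfDNA alt reads from Binomial(cf_depth, vaf) on top of
#' a sequencing-error floor, with error-only germline alt reads; germline
#' heterozygous sites draw alt reads at VAF 0.5 in both tissues (these are
#' the constitutional polymorphisms the germline filter must remove).
#'
#' @param n_sites Number of somatic candidate sites.
#' @param true_somatic_vafs True cfDNA VAFs, recycled over sites (0 = no
#'   somatic signal).
#' @param cf_depth,g_depth Sequencing depths (recycled).
#' @param germline_het_sites Number of additional constitutional het sites.
#' @param base_error Per-base sequencing error rate (default 0.001).
#' @param seed RNG seed.
#' @param sample_id,timepoint Metadata columns.
#' @return A variant-record data frame with a logical `true_somatic` column.
#' @export
simulate_variant_table <- function(n_sites, true_somatic_vafs, cf_depth = 100,
                                   g_depth = 100, germline_het_sites = 0,
                                   base_error = 0.001, seed = 1,
                                   sample_id = "SIM", timepoint = "na") {
  vaf <- rep_len(true_somatic_vafs, n_sites)
  if (any(vaf < 0 | vaf >= 1)) stopf("VAFs must be in [0, 1)")
  n <- n_sites + germline_het_sites
  cf_d <- rep_len(cf_depth, n)
  g_d <- rep_len(g_depth, n)
  p_cf <- c(pmin(vaf + base_error, 1), rep(0.5, germline_het_sites))
  p_g <- c(rep(base_error, n_sites), rep(0.5, germline_het_sites))
  draws <- with_seed(seed, {
    list(cf = stats::rbinom(n, cf_d, p_cf), g = stats::rbinom(n, g_d, p_g))
  })
  data.frame(
    gene = sprintf("GENE%04d", seq_len(n)),
    chrom = "sim1", pos = seq_len(n) * 1000L,
    ref = "A", alt = "T",
    cf_depth = cf_d, cf_alt = draws$cf, g_depth = g_d, g_alt = draws$g,
    sample_id = sample_id, timepoint = timepoint,
    true_somatic = c(vaf > 0, rep(FALSE, germline_het_sites)),
    stringsAsFactors = FALSE)
}
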