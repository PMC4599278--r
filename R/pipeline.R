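#' Pipeline run configuration
#'
#' Collects every input path and tunable knob of the end-to-end analysis.
#' All knobs have defaults; the effective configuration is serialized into
#' the output directory's manifest so every run is self-describing.
#'
#' @param input_dir Directory in the layout written by [write_cohort()]:
#'   `bins.bed`, `samples.tsv`, `clinical.tsv`, `counts/`.
#' @param out_dir Output directory.
#' @param variants_file Optional variant TSV (all samples stacked, with
#'   `sample_id` and `timepoint` columns).
#' @param gene_sets_file Optional GMT file for pathway-shift analysis.
#' @param seed Seed (segmentation permutations).
#' @param min_germline_count,gc_span,pga_cutoff,segment_alpha,n_perm,
#'   vaf_cutoff,min_cf_depth,max_germline_vaf,min_g_depth,
#'   gain_threshold,loss_threshold Module knobs (see the corresponding
#'   functions for semantics and defaults).
#' @param segment Run segmentation per profile (default TRUE).
#' @param min_score_bins Minimum usable bins for PGA scoring (default 100).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            variants_file = NULL, gene_sets_file = NULL,
                            seed = 1, min_germline_count = 100,
                            gc_span = 0.3, pga_cutoff = 10,
                            segment_alpha = 0.01, n_perm = 1000,
                            vaf_cutoff = 0.02, min_cf_depth = 50,
                            max_germline_vaf = 0.01, min_g_depth = 20,
                            gain_threshold = 0.2, loss_threshold = -0.2,
                            segment = TRUE, min_score_bins = 100) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 variants_file = variants_file, gene_sets_file = gene_sets_file,
                 seed = seed, min_germline_count = min_germline_count,
                 gc_span = gc_span, pga_cutoff = pga_cutoff,
                 segment_alpha = segment_alpha, n_perm = n_perm,
                 vaf_cutoff = vaf_cutoff, min_cf_depth = min_cf_depth,
                 max_germline_vaf = max_germline_vaf, min_g_depth = min_g_depth,
                 gain_threshold = gain_threshold, loss_threshold = loss_threshold,
                 segment = segment, min_score_bins = min_score_bins),
            class = "run_config")
}

#' Run the end-to-end cfDNA analysis
#'
#' From per-bin count tables to reports: normalization, matched-germline
#' log2 ratios, GC correction, PGA scores and classifications, TEff indexes,
#' optional segmentation, optional somatic calls and pathway shifts, and a
#' survival-table export. Re-running with the same configuration and seed
#' reproduces byte-identical TSVs. On failure, partially written outputs are
#' removed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the scores, teff and (when computed)
#'   somatic/pathway tables; all reports are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  ind <- config$input_dir
  out <- config$out_dir
  written <- character()
  keep <- function(p) { written <<- c(written, p); p }
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    bins <- read_bin_set(file.path(ind, "bins.bed"))
    samples <- utils::read.delim(file.path(ind, "samples.tsv"), stringsAsFactors = FALSE)
    clinical_path <- file.path(ind, "clinical.tsv")
    clinical <- if (file.exists(clinical_path))
      utils::read.delim(clinical_path, stringsAsFactors = FALSE) else NULL

    dir.create(file.path(out, "profiles"), recursive = TRUE, showWarnings = FALSE)
    if (config$segment)
      dir.create(file.path(out, "segments"), recursive = TRUE, showWarnings = FALSE)

    counts <- lapply(seq_len(nrow(samples)), function(i) {
      load_counts_table(file.path(ind, samples$path[i]), bins,
                        sample_id = samples$sample_id[i],
                        patient_id = samples$patient_id[i],
                        role = samples$role[i],
                        timepoint = samples$timepoint[i])
    })
    names(counts) <- samples$sample_id

    germline_of <- function(pid) {
      hit <- which(samples$patient_id == pid & samples$role == "germline")
      if (length(hit) == 0L)
        stopf("no matched germline sample for patient %s", pid)
      counts[[hit[1]]]
    }

    plasma_idx <- which(samples$role == "plasma")
    score_rows <- list()
    for (i in plasma_idx) {
      pl <- normalize_global_mean(counts[[i]])
      gl <- normalize_global_mean(germline_of(pl$patient_id))
      prof <- log2_ratio(pl, gl, min_germline_count = config$min_germline_count)
      prof <- gc_correct(prof, span = config$gc_span)
      tag <- paste0(prof$patient_id, "_", prof$timepoint)
      keep(write_profile(prof, file.path(out, "profiles", paste0(tag, ".tsv"))))
      if (config$segment) {
        segs <- segment_profile(prof, alpha = config$segment_alpha,
                                n_perm = config$n_perm, seed = config$seed)
        keep(write_segments(segs, file.path(out, "segments", paste0(tag, ".tsv"))))
      }
      res <- pga_score(prof, min_bins = config$min_score_bins)
      row <- as.data.frame(res)
      row$classification <- classify_pga(res, cutoff = config$pga_cutoff)
      score_rows[[tag]] <- row
    }
    scores <- do.call(rbind, score_rows)
    rownames(scores) <- NULL
    utils::write.table(scores, keep(file.path(out, "scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    teff <- compute_teff_table(scores)
    utils::write.table(teff, keep(file.path(out, "teff.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    somatic <- pathways <- NULL
    if (!is.null(config$variants_file)) {
      records <- read_variant_table(config$variants_file)
      calls <- lapply(split(records, paste(records$sample_id, records$timepoint)),
                      call_somatic,
                      vaf_cutoff = config$vaf_cutoff,
                      min_cf_depth = config$min_cf_depth,
                      max_germline_vaf = config$max_germline_vaf,
                      min_g_depth = config$min_g_depth)
      somatic <- do.call(rbind, lapply(calls, function(x) x$calls))
      rownames(somatic) <- NULL
      utils::write.table(somatic, keep(file.path(out, "somatic_calls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(config$gene_sets_file)) {
        gs <- read_gene_sets(config$gene_sets_file)
        pre_genes <- unique(unlist(lapply(calls, function(x)
          if (x$timepoint == "pre") x$mutated_genes)))
        post_genes <- unique(unlist(lapply(calls, function(x)
          if (x$timepoint == "post") x$mutated_genes)))
        pathways <- pathway_shift(pre_genes %||% character(),
                                  post_genes %||% character(), gs)
        utils::write.table(pathways, keep(file.path(out, "pathway_shift.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    if (!is.null(clinical)) {
      surv <- export_survival_table(scores, clinical,
                                    path = keep(file.path(out, "survival.tsv")))
    } else surv <- NULL

    manifest <- list(
      package = "plasmaPGA",
      version = as.character(utils::packageVersion("plasmaPGA")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config = config[setdiff(names(config), c())],
      n_samples = nrow(samples),
      n_bins = nrow(bins))
    jsonlite::write_json(manifest, keep(file.path(out, "manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(list(scores = scores, teff = teff, somatic = somatic,
                   pathways = pathways, survival = surv))
  }, error = on_fail)
}

# Join pre/post PGA rows per patient into a TEff table
compute_teff_table <- function(scores) {
  pre <- scores[scores$timepoint == "pre", , drop = FALSE]
  post <- scores[scores$timepoint == "post", , drop = FALSE]
  pids <- intersect(pre$patient_id, post$patient_id)
  rows <- lapply(pids, function(pid) {
    t <- teff_index(pre$pga[pre$patient_id == pid][1],
                    post$pga[post$patient_id == pid][1])
    data.frame(patient_id = pid, pre_pga = t$pre_pga, post_pga = t$post_pga,
               teff = t$teff, stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), pre_pga = numeric(),
               post_pga = numeric(), teff = numeric())
}

#' Export a per-patient survival table
#'
#' Joins PGA scores, TEff indexes and classifications with the clinical
#' sheet's follow-up columns, one row per patient, for external survival
#' analysis. Patients missing from either side are retained with `NA`
#' fields and a warning.
#'
#' @param scores Score table as produced by [run_pipeline()] (columns
#'   `patient_id`, `timepoint`, `pga`, `classification`).
#' @param clinical Clinical sheet data frame (`patient_id`, `vital_status`,
#'   `followup_months`, ...).
#' @param path Optional output TSV path.
#' @return The joined data frame.
#' @export
export_survival_table <- function(scores, clinical, path = NULL) {
  pids <- union(unique(scores$patient_id), clinical$patient_id)
  rows <- lapply(pids, function(pid) {
    pre <- scores[scores$patient_id == pid & scores$timepoint == "pre", , drop = FALSE]
    post <- scores[scores$patient_id == pid & scores$timepoint == "post", , drop = FALSE]
    cl <- clinical[clinical$patient_id == pid, , drop = FALSE]
    if (nrow(cl) == 0L || (nrow(pre) == 0L && nrow(post) == 0L))
      warning(sprintf("patient %s present on only one side of the join", pid),
              call. = FALSE)
    teff <- if (nrow(pre) && nrow(post) && pre$pga[1] > 0 && post$pga[1] > 0)
      teff_index(pre$pga[1], post$pga[1])$teff else NA_real_
    data.frame(
      patient_id = pid,
      pre_pga = if (nrow(pre)) pre$pga[1] else NA_real_,
      post_pga = if (nrow(post)) post$pga[1] else NA_real_,
      teff = teff,
      classification = if (nrow(pre)) pre$classification[1] else NA_character_,
      vital_status = if (nrow(cl)) cl$vital_status[1] else NA,
      followup_months = if (nrow(cl)) cl$followup_months[1] else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), pre_pga = numeric(),
               post_pga = numeric(), teff = numeric(),
               classification = character(), vital_status = integer(),
               followup_months = numeric())
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
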