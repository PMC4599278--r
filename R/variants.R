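#' Read a variant table (TSV)
#'
#' Expects columns `gene`, `chrom`, `pos`, `ref`, `alt`, `cf_depth`,
#' `cf_alt`, `g_depth`, `g_alt` and optionally `sample_id`, `timepoint`:
#' per-site read depths and alt-allele counts in cfDNA and the matched
#' lymphocyte germline DNA.
#'
#' @param path TSV path.
#' @return A data frame of variant records.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "pos", "ref", "alt",
            "cf_depth", "cf_alt", "g_depth", "g_alt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("variant table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(tab$cf_alt > tab$cf_depth | tab$g_alt > tab$g_depth, na.rm = TRUE))
    stopf("alt count exceeds depth in variant table")
  tab
}

#' Write a variant table (TSV)
#' @param records Variant record data frame.
#' @param path Output path.
#' @export
write_variant_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cfDNA/germline variant records from a VCF
#'
#' Pulls per-sample AD (ref,alt) and DP FORMAT fields for a cfDNA sample and
#' its matched germline sample; the gene symbol is taken from the `GENE` INFO
#' field. Multi-allelic records use the first alternate allele.
#'
#' @param path VCF path.
#' @param cf_sample,g_sample Sample names in the VCF.
#' @param sample_id,timepoint Metadata for the resulting records.
#' @return A data frame of variant records as in [read_variant_table()].
#' @export
read_variant_vcf <- function(path, cf_sample, g_sample,
                             sample_id = cf_sample, timepoint = "na") {
  vcf <- VariantAnnotation::readVcf(path)
  smp <- colnames(vcf)
  if (!all(c(cf_sample, g_sample) %in% smp))
    stopf("sample(s) not in VCF: %s",
          paste(setdiff(c(cf_sample, g_sample), smp), collapse = ", "))
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  if (is.null(ad)) stopf("VCF has no AD FORMAT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  gene <- VariantAnnotation::info(vcf)$GENE
  if (is.null(gene)) gene <- rep(NA_character_, length(rr))
  alt1 <- function(i, s) {
    v <- ad[i, s][[1]]
    if (length(v) >= 2) v[2] else 0L
  }
  n <- length(rr)
  data.frame(
    gene = as.character(gene),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(seq_len(n), function(i) as.character(rr$ALT[[i]][1]), ""),
    cf_depth = as.integer(dp[, cf_sample]),
    cf_alt = vapply(seq_len(n), alt1, 0L, s = cf_sample),
    g_depth = as.integer(dp[, g_sample]),
    g_alt = vapply(seq_len(n), alt1, 0L, s = g_sample),
    sample_id = sample_id, timepoint = timepoint,
    stringsAsFactors = FALSE)
}

#' Call somatic mutations by cfDNA VAF against the matched germline
#'
#' A record is called somatic iff its cfDNA variant allele fraction
#' `cf_alt/cf_depth >= vaf_cutoff` (2% by default), its depths satisfy the
#' floors, and the germline VAF is at most `max_germline_vaf` (removing
#' constitutional polymorphisms). Zero-depth records are excluded with a
#' warning, not an error.
#'
#' @param records Variant records from one sample ([read_variant_table()] /
#'   [read_variant_vcf()]).
#' @param vaf_cutoff Minimum cfDNA VAF (default 0.02).
#' @param min_cf_depth Minimum cfDNA depth (default 50).
#' @param max_germline_vaf Maximum germline VAF (default 0.01).
#' @param min_g_depth Minimum germline depth (default 20).
#' @param sample_id,timepoint Metadata; defaults come from the records.
#' @return A `somatic_calls` object with fields `calls` (the passing
#'   records), `mutated_genes`, and the filter parameters used.
#' @export
call_somatic <- function(records, vaf_cutoff = 0.02, min_cf_depth = 50,
                         max_germline_vaf = 0.01, min_g_depth = 20,
                         sample_id = NULL, timepoint = NULL) {
  sample_id <- sample_id %||% (records$sample_id[1] %||% NA_character_)
  timepoint <- timepoint %||% (records$timepoint[1] %||% "na")
  zero <- records$cf_depth == 0 | records$g_depth == 0
  if (any(zero)) {
    warning(sprintf("%d zero-depth record(s) excluded", sum(zero)), call. = FALSE)
    records <- records[!zero, , drop = FALSE]
  }
  pass <- records$cf_alt / records$cf_depth >= vaf_cutoff &
    records$cf_depth >= min_cf_depth &
    records$g_depth >= min_g_depth &
    records$g_alt / records$g_depth <= max_germline_vaf
  calls <- records[pass, , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(sample_id = sample_id, timepoint = timepoint,
                 calls = calls,
                 mutated_genes = sort(unique(calls$gene[!is.na(calls$gene)])),
                 params = list(vaf_cutoff = vaf_cutoff,
                               min_cf_depth = min_cf_depth,
                               max_germline_vaf = max_germline_vaf,
                               min_g_depth = min_g_depth)),
            class = "somatic_calls")
}

#' @export
print.somatic_calls <- function(x, ...) {
  cat(sprintf("somatic_calls: %s (timepoint %s)\n", x$sample_id, x$timepoint))
  cat(sprintf("  %d variant(s) in %d gene(s); VAF cutoff %.3f, cfDNA depth >= %d, germline VAF <= %.3f at depth >= %d\n",
              nrow(x$calls), length(x$mutated_genes), x$params$vaf_cutoff,
              x$params$min_cf_depth, x$params$max_germline_vaf, x$params$min_g_depth))
  invisible(x)
}

# Coerce a somatic_calls object or character vector to a gene set
gene_set_of <- function(x) {
  if (inherits(x, "somatic_calls")) x$mutated_genes else unique(as.character(x))
}

#' Compare mutated-gene sets between timepoints
#'
#' Partitions the union of the pre- and post-treatment mutated genes into
#' shared, pre-only and post-only sets.
#'
#' @param pre,post `somatic_calls` objects or character vectors of genes.
#' @return A list with `shared`, `pre_only`, `post_only` and a `counts`
#'   vector.
#' @export
compare_timepoints <- function(pre, post) {
  a <- gene_set_of(pre)
  b <- gene_set_of(post)
  out <- list(shared = sort(intersect(a, b)),
              pre_only = sort(setdiff(a, b)),
              post_only = sort(setdiff(b, a)))
  out$counts <- c(shared = length(out$shared),
                  pre_only = length(out$pre_only),
                  post_only = length(out$post_only),
                  pre_total = length(a), post_total = length(b))
  out
}

#' Read gene sets from a GMT file
#' @param path GMT path (set name, description, member genes per line).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) stopf("empty GMT file: %s", path)
  sets
}

#' Pre/post-treatment pathway shifts in mutated genes
#'
#' For each pathway, counts the mutated genes at each timepoint after
#' intersecting the pathway with the background gene universe (e.g. the
#' targeted panel), and flags pathways whose absolute difference in mutated
#' gene counts strictly exceeds `delta_cutoff` (default 3).
#'
#' @param pre_genes,post_genes Mutated-gene sets (`somatic_calls` or
#'   character vectors).
#' @param gene_sets Named list of pathways ([read_gene_sets()]).
#' @param background Gene universe to intersect pathways with; defaults to
#'   the union of all pathway genes.
#' @param delta_cutoff Strict threshold on |n_post - n_pre| (default 3).
#' @return A data frame sorted by `delta` descending: `pathway`,
#'   `n_genes_in_pathway`, `n_pre`, `n_post`, `delta`, `flagged`.
#' @export
pathway_shift <- function(pre_genes, post_genes, gene_sets,
                          background = NULL, delta_cutoff = 3) {
  if (length(gene_sets) == 0L) stopf("empty gene set collection")
  pre <- gene_set_of(pre_genes)
  post <- gene_set_of(post_genes)
  background <- background %||% unique(unlist(gene_sets))
  rows <- lapply(names(gene_sets), function(nm) {
    pw <- intersect(gene_sets[[nm]], background)
    n_pre <- length(intersect(pre, pw))
    n_post <- length(intersect(post, pw))
    data.frame(pathway = nm, n_genes_in_pathway = length(pw),
               n_pre = n_pre, n_post = n_post,
               delta = abs(n_post - n_pre),
               flagged = abs(n_post - n_pre) > delta_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
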