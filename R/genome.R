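#' Read a UCSC-style chrom.sizes file
#'
#' Parses a two-column whitespace-delimited file of chromosome names and
#' lengths, preserving file order.
#'
#' @param path Path to a chrom.sizes file (columns: name, length in bp).
#' @param include Optional character vector of chromosome names to keep;
#'   chromosomes are returned in file order regardless of the order given here.
#' @return A `chrom_sizes` object: a data frame with columns `chrom` and
#'   `length`.
#' @examples
#' cs <- read_chrom_sizes(system.file("extdata", "hg19.chrom.sizes",
#'                                    package = "plasmaPGA"))
#' nrow(cs)  # 24 (chr1-22, X, Y)
#' @export
read_chrom_sizes <- function(path, include = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty chrom.sizes file: %s", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) stopf("malformed chrom.sizes line %d: '%s'", bad[1], lines[bad[1]])
  chrom <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(len) | len <= 0 | len != floor(len))
  if (length(bad)) stopf("malformed chromosome length on line %d: '%s'", bad[1], lines[bad[1]])
  dup <- chrom[duplicated(chrom)]
  if (length(dup)) stopf("duplicate chromosome name(s): %s", paste(unique(dup), collapse = ", "))
  sizes <- data.frame(chrom = chrom, length = len, stringsAsFactors = FALSE)
  if (!is.null(include)) sizes <- sizes[sizes$chrom %in% include, , drop = FALSE]
  rownames(sizes) <- NULL
  structure(sizes, class = c("chrom_sizes", "data.frame"))
}

#' Tile a genome into fixed-width bins
#'
#' Partitions each chromosome into consecutive windows of `bin_size` bp,
#' 0-based half-open (BED convention). The final window on each chromosome is
#' truncated at the chromosome end, so a chromosome of length L contributes
#' `ceiling(L / bin_size)` bins. With the bundled hg19 chr1-22,X,Y sizes and
#' 1 Mb bins this yields 3113 bins, the coordinate system the log2-ratio
#' profiles and PGA scores live on.
#'
#' @param sizes A `chrom_sizes` object from [read_chrom_sizes()] (or a data
#'   frame with columns `chrom`, `length`).
#' @param bin_size Window width in bp (default 1e6).
#' @param genome_label Free-text genome label stored with the bin set.
#' @return A `bin_set` object: a data frame with columns `chrom`, `start`,
#'   `end`, `gc` (NA until [annotate_gc()]), plus attributes `bin_size`,
#'   `genome_label` and `chrom_order`.
#' @export
tile_genome <- function(sizes, bin_size = 1e6, genome_label = "") {
  if (nrow(sizes) == 0L) stopf("no chromosomes to tile")
  if (!is.numeric(bin_size) || bin_size <= 0) stopf("bin_size must be > 0")
  pieces <- lapply(seq_len(nrow(sizes)), function(i) {
    len <- sizes$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = sizes$chrom[i],
               start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$gc <- NA_real_
  rownames(bins) <- NULL
  structure(bins,
            bin_size = bin_size,
            genome_label = genome_label,
            chrom_order = sizes$chrom,
            class = c("bin_set", "data.frame"))
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set: %d bins of %s bp on %d chromosome(s)%s\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(attr(x, "chrom_order")),
              if (nzchar(attr(x, "genome_label") %||% ""))
                paste0(" [", attr(x, "genome_label"), "]") else ""))
  cat(sprintf("  GC annotated: %s\n",
              if (all(is.na(x$gc))) "no" else sprintf("%d bins", sum(!is.na(x$gc)))))
  invisible(x)
}

#' Annotate bins with GC fraction
#'
#' GC fraction per bin is (G+C) / (non-N bases); all-N bins get `NA`. The
#' source is either a FASTA file (sequence names matched to bin chromosomes)
#' or a per-bin GC table keyed by (chrom, start).
#'
#' @param bins A `bin_set`.
#' @param fasta Path to a FASTA file covering the bin chromosomes.
#' @param gc_table A data frame (or TSV path) with columns `chrom`, `start`,
#'   `gc`; every bin must be present.
#' @return The `bin_set` with its `gc` column filled.
#' @export
annotate_gc <- function(bins, fasta = NULL, gc_table = NULL) {
  if (is.null(fasta) == is.null(gc_table))
    stopf("supply exactly one of `fasta` or `gc_table`")
  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    missing_chr <- setdiff(unique(bins$chrom), names(seqs))
    if (length(missing_chr))
      stopf("chromosome(s) absent from FASTA: %s", paste(missing_chr, collapse = ", "))
    gc <- rep(NA_real_, nrow(bins))
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      v <- Biostrings::Views(seqs[[ch]], start = bins$start[idx] + 1L, end = bins$end[idx])
      freq <- Biostrings::letterFrequency(v, c("G", "C", "N"))
      denom <- (bins$end[idx] - bins$start[idx]) - freq[, "N"]
      gc[idx] <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
    }
    bins$gc <- gc
  } else {
    tab <- if (is.character(gc_table)) {
      utils::read.delim(gc_table, comment.char = "#", stringsAsFactors = FALSE)
    } else gc_table
    need <- c("chrom", "start", "gc")
    if (!all(need %in% names(tab)))
      stopf("GC table needs columns: %s", paste(need, collapse = ", "))
    key <- paste(bins$chrom, bins$start)
    m <- match(key, paste(tab$chrom, tab$start))
    if (anyNA(m)) {
      miss <- key[is.na(m)]
      stopf("GC table missing %d bin(s), e.g. %s", length(miss),
            paste(utils::head(miss, 3), collapse = "; "))
    }
    bins$gc <- tab$gc[m]
  }
  bins
}

#' Write a bin set as a BED-like TSV
#'
#' Columns chrom, start, end, gc; 0-based half-open coordinates, stated in the
#' file's comment header.
#' @param bins A `bin_set`.
#' @param path Output path.
#' @export
write_bin_set <- function(bins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, list(bin_size = attr(bins, "bin_size"),
                              genome_label = attr(bins, "genome_label")))
  utils::write.table(as.data.frame(bins)[c("chrom", "start", "end", "gc")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin set written by [write_bin_set()]
#' @param path Path to the TSV.
#' @export
read_bin_set <- function(path) {
  meta <- read_meta_header(path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(tab[c("chrom", "start", "end", "gc")],
            bin_size = as.numeric(meta$bin_size %||% max(tab$end - tab$start)),
            genome_label = meta$genome_label %||% "",
            chrom_order = unique(tab$chrom),
            class = c("bin_set", "data.frame"))
}

# TRUE when two bin sets describe the same tiling
same_bins <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) && all(a$start == b$start)
}

#' Path to the bundled hg19 chrom.sizes (chr1-22, X, Y)
#' @export
hg19_chrom_sizes_path <- function() {
  system.file("extdata", "hg19.chrom.sizes", package = "plasmaPGA")
}
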