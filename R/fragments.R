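#' Construct a fragment table
#'
#' Fragments are the unit of chromatin-profiling signal: one aligned
#' (paired-end) fragment per row, in BED convention (0-based, half-open).
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector of 0-based inclusive start positions.
#' @param end integer vector of exclusive end positions.
#' @param strand optional character vector ("+"/"-"), required only for
#'   single-end read extension.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (and
#'   `strand` when supplied).
#' @export
fragments <- function(chrom, start, end, strand = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stop("chrom, start and end must have equal length")
  }
  if (any(start < 0)) stop("fragment start must be >= 0")
  if (any(end <= start)) stop("fragment end must be > start")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (length(strand) != length(chrom)) stop("strand length mismatch")
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    out$strand <- strand
  }
  out
}

empty_fragments <- function(strand = FALSE) {
  out <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), stringsAsFactors = FALSE)
  if (strand) out$strand <- character(0)
  out
}

#' Filter fragments by length
#'
#' Retains fragments whose length lies within a closed interval, e.g.
#' 120-500 bp for CUT&RUN or 120-1000 bp for CUT&Tag.  Both bounds are
#' inclusive and input order is preserved.
#'
#' @param frags fragment `data.frame` (see [fragments()]).
#' @param min_len,max_len inclusive length bounds in bp.
#' @return The retained fragments.
#' @export
filter_fragments <- function(frags, min_len = 120, max_len = 500) {
  stopifnot(min_len <= max_len)
  len <- frags$end - frags$start
  frags[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Remove coordinate duplicates
#'
#' Discards fragments having the same chromosome, start and end
#' coordinates as an earlier fragment (the presumed PCR duplicates of
#' tagmentation-based assays); the first occurrence is kept.
#'
#' @param frags fragment `data.frame`.
#' @return Fragments with at most one row per (chrom, start, end).
#' @export
dedup_fragments <- function(frags) {
  key <- paste(frags$chrom, frags$start, frags$end, sep = "\r")
  frags[!duplicated(key), , drop = FALSE]
}

#' Extend single-end reads into fragments
#'
#' Each read is extended from its 5' alignment start in the strand
#' direction to a fixed total fragment length (default 250 bp, the
#' fragment size of typical sonicated ChIP libraries).  Resulting
#' fragments are clipped to chromosome bounds.
#'
#' @param reads fragment `data.frame` carrying a `strand` column.
#' @param extension total fragment length in bp after extension.
#' @param chrom_sizes named vector of chromosome lengths for clipping.
#' @return fragment `data.frame` (strand retained).
#' @export
extend_single_end <- function(reads, extension = 250, chrom_sizes = NULL) {
  if (nrow(reads) == 0) return(reads)
  if (is.null(reads$strand)) stop("reads must carry a strand column")
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$end - extension)
  end <- ifelse(plus, reads$start + extension, reads$end)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
    if (length(unknown) > 0) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    }
    end <- pmin(end, unname(chrom_sizes[reads$chrom]))
  }
  fragments(reads$chrom, start, end, strand = reads$strand)
}

#' Read fragments from a BED file
#'
#' Accepts 3- or 6-column BED (0-based, half-open).  Column 6, when
#' present, is taken as strand.
#'
#' @param path BED file path (plain text or gzip).
#' @return fragment `data.frame`.
#' @export
read_fragments_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = paste0("V", 1:6), fill = TRUE)
  if (nrow(tab) == 0) return(empty_fragments())
  strand <- NULL
  if (all(tab$V6 %in% c("+", "-")) && !any(is.na(tab$V6)) &&
      !any(tab$V6 == "")) {
    strand <- tab$V6
  }
  fragments(tab$V1, as.numeric(tab$V2), as.numeric(tab$V3), strand = strand)
}

#' Write fragments as 3-column BED
#'
#' @param frags fragment `data.frame`.
#' @param path output path; `.gz` suffix writes gzip.
#' @export
write_fragments_bed <- function(frags, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(
    frags[, c("chrom", "start", "end"), drop = FALSE], con,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' @param path two-column TSV (chromosome name, length in bp).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Write a chromosome-sizes table
#'
#' @param chrom_sizes named numeric vector.
#' @param path output TSV path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(
    data.frame(names(chrom_sizes), unname(chrom_sizes)), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# BED data.frame (0-based half-open) <-> GRanges (1-based closed)
bed_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

gr_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
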