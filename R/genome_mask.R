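#' Genome interval mask
#'
#' A set of genomic intervals used either as a positive (callable) mask or a
#' repeat mask. Intervals are supplied in BED convention (0-based,
#' half-open) and normalized (sorted, merged) on construction. A 1-based
#' variant position `p` lies inside interval `[start, end)` iff
#' `start < p <= end`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open interval bounds
#'   (`end > start`).
#' @param role `"positive"` or `"repeat"`.
#' @return A `genome_mask` wrapping a normalized
#'   [GenomicRanges::GRanges] (1-based, closed).
#' @export
genome_mask <- function(chrom, start, end, role = c("positive", "repeat")) {
  role <- match.arg(role)
  if (any(end <= start)) stop("mask intervals require end > start")
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1L, end = end)))
  structure(list(ranges = gr, role = role), class = "genome_mask")
}

#' @export
print.genome_mask <- function(x, ...) {
  cat("genome_mask (", x$role, "): ", length(x$ranges), " intervals, ",
      sum(IRanges::width(x$ranges)), " bp\n", sep = "")
  invisible(x)
}

#' Read a BED file as a genome mask
#'
#' @param path BED file (3+ columns; extra columns ignored).
#' @inheritParams genome_mask
#' @return A [genome_mask()].
#' @export
read_mask_bed <- function(path, role = c("positive", "repeat")) {
  role <- match.arg(role)
  gr <- rtracklayer::import(path, format = "BED")
  structure(list(ranges = GenomicRanges::reduce(GenomicRanges::granges(gr)),
                 role = role), class = "genome_mask")
}

#' Write a genome mask as BED
#'
#' @param mask a [genome_mask()].
#' @param path output path (0-based half-open records).
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(mask, path) {
  gr <- mask$ranges
  write.table(
    data.frame(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## TRUE for each (chrom, pos) covered by the mask; chromosomes absent from
## the mask yield FALSE.
mask_covers <- function(mask, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(
    q, mask$ranges, ignore.strand = TRUE) > 0L
}

## Masked bp inside a half-open window [wstart, wend) (0-based) on chrom.
mask_bp_in_window <- function(mask, chrom, wstart, wend) {
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(wstart + 1L, wend))
  sum(IRanges::width(GenomicRanges::intersect(
    mask$ranges[GenomicRanges::seqnames(mask$ranges) == chrom], win)))
}
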