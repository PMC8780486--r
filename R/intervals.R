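#' Genomic intervals
#'
#' Intervals are plain data frames with columns \code{chrom}, \code{start},
#' \code{end}, 1-based and inclusive at both ends (the convention of the
#' printed hg19 coordinates this package works with). Conversion to the
#' 0-based half-open BED convention happens only in \code{\link{write_cnv_bed}}.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 1-based inclusive; \code{end >= start}.
#' @return a data.frame with columns chrom/start/end.
#' @examples
#' genomic_interval("chr1", 1392270, 1460317)
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 1L)) {
    stop("interval start must be a positive integer")
  }
  if (any(end < start)) stop("interval end must be >= start")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Interval span in bases (1-based inclusive: end - start + 1)
#' @param x interval data.frame.
#' @return integer vector of spans.
#' @export
interval_span <- function(x) x$end - x$start + 1L

# data.frame intervals -> GRanges (same 1-based inclusive coordinates).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end)
  )
}

#' Reciprocal overlap of two interval sets, pairwise
#'
#' Two intervals overlap reciprocally at threshold t when the shared
#' length is at least t of each interval's own span.
#'
#' @param a,b interval data.frames of equal row count (compared row-wise).
#' @return numeric vector: min(overlap/span(a), overlap/span(b)), 0 when
#'   disjoint or on different chromosomes.
#' @export
reciprocal_overlap <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  ov <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start) + 1L)
  ov[a$chrom != b$chrom] <- 0L
  pmin(ov / interval_span(a), ov / interval_span(b))
}
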