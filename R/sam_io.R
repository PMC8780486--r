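#' Read primary alignment records from a SAM/BAM file
#'
#' Returns one row per primary alignment line (secondary and supplementary
#' alignments are excluded) with the fields the discordant-pair CNV caller
#' consumes: position, mapping quality, signed template length (TLEN) and
#' pair orientation. SAM input is converted to BAM internally via
#' \pkg{Rsamtools}; the input is expected to be coordinate-sorted, as
#' produced by the aligner or by \code{\link{simulate_read_pairs}}.
#'
#' @param path SAM (".sam") or BAM file.
#' @param region optional single-row interval data.frame
#'   (\code{\link{genomic_interval}}); restricts to overlapping records.
#'   The region chromosome must be declared in the header.
#' @return data.frame with columns \code{read_id}, \code{chrom},
#'   \code{pos} (1-based leftmost), \code{mapq}, \code{tlen},
#'   \code{is_reverse}, \code{mate_is_reverse}, \code{is_first_in_pair}.
#' @examples
#' sim <- simulate_read_pairs(n_background_pairs = 50, seed = 1)
#' sam <- tempfile(fileext = ".sam")
#' writeLines(sim$sam_lines, sam)
#' pairs <- read_sam_pairs(sam)
#' nrow(pairs)  # two records per pair
#' @export
read_sam_pairs <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    validate_sam_lines(path)
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "isize")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  } else {
    stopifnot(nrow(region) == 1L)
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (!(region$chrom %in% names(hdr))) {
      stop("region chromosome '", region$chrom,
           "' is not declared in the alignment header")
    }
    param <- Rsamtools::ScanBamParam(flag = flag, what = what,
                                     which = as_granges(region))
  }
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  fl <- res$flag %||% integer(0)
  data.frame(
    read_id = as.character(res$qname %||% character(0)),
    chrom = as.character(res$rname %||% character(0)),
    pos = as.integer(res$pos %||% integer(0)),
    mapq = as.integer(res$mapq %||% integer(0)),
    tlen = as.integer(res$isize %||% integer(0)),
    is_reverse = bitwAnd(fl, 16L) > 0L,
    mate_is_reverse = bitwAnd(fl, 32L) > 0L,
    is_first_in_pair = bitwAnd(fl, 64L) > 0L,
    stringsAsFactors = FALSE
  )
}

# Cheap structural check so a malformed alignment line is reported with
# its line number rather than as an opaque conversion failure.
validate_sam_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "@")
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 11L)) {
    bad <- which(body)[which(nf < 11L)[1]]
    stop("malformed SAM line ", bad, ": fewer than 11 mandatory fields")
  }
  invisible(TRUE)
}
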