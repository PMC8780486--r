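#' Write CNV calls as BED6
#'
#' Internal coordinates are 1-based inclusive; on output they are
#' converted to the BED convention (0-based start, half-open end). The
#' name column encodes \code{type:support:source}; the score column
#' carries the rank (0 when unranked).
#'
#' @param calls CNV call data.frame (columns chrom, start, end, sv_type,
#'   support, source and optionally rank), e.g. from
#'   \code{\link{call_cnv_discordant}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_cnv_bed <- function(calls, path) {
  header <- "# cardiotrio CNV calls; name = type:support:source"
  if (is.null(calls) || nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  rank <- if ("rank" %in% names(calls)) calls$rank else rep(0L, nrow(calls))
  lines <- sprintf("%s\t%d\t%d\t%s:%d:%s\t%d\t.",
                   calls$chrom, calls$start - 1L, calls$end,
                   calls$sv_type, calls$support, calls$source, rank)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read CNV calls written by \code{\link{write_cnv_bed}}
#'
#' @param path BED file produced by \code{\link{write_cnv_bed}}.
#' @return CNV call data.frame in 1-based inclusive coordinates.
#' @export
read_cnv_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sv_type = character(0),
                      support = integer(0), source = character(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  name <- vapply(f, `[[`, "", 4L)
  meta <- strsplit(name, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 2L)) + 1L,
    end = as.integer(vapply(f, `[[`, "", 3L)),
    sv_type = vapply(meta, `[[`, "", 1L),
    support = as.integer(vapply(meta, `[[`, "", 2L)),
    source = vapply(meta, `[[`, "", 3L),
    rank = as.integer(vapply(f, `[[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}
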