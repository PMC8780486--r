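#' Configuration of the depth caller and the dual-pipeline consensus
#'
#' @param reciprocal_overlap fraction in (0, 1]: minimum reciprocal
#'   overlap for a discordant-pair call and a depth call to agree.
#' @param ratio_dup,ratio_del normalized depth-ratio gates (> 1 / < 1).
#' @param min_consecutive_targets minimum run length of concordant
#'   targets per depth call.
#' @param z_threshold robust z-score gate.
#' @return list of class \code{consensus_config}.
#' @export
consensus_config <- function(reciprocal_overlap = 0.5, ratio_dup = 1.3,
                             ratio_del = 0.7, min_consecutive_targets = 2L,
                             z_threshold = 3) {
  stopifnot(reciprocal_overlap > 0, reciprocal_overlap <= 1,
            ratio_del < 1, ratio_dup > 1, min_consecutive_targets >= 1)
  structure(list(reciprocal_overlap = reciprocal_overlap,
                 ratio_dup = ratio_dup, ratio_del = ratio_del,
                 min_consecutive_targets = as.integer(min_consecutive_targets),
                 z_threshold = z_threshold),
            class = "consensus_config")
}

#' Read-depth CNV calls (simplified stand-in for the depth pipeline)
#'
#' Library-size-normalized case counts are compared per target with the
#' reference-panel mean; a robust z-score uses a pooled coefficient of
#' variation (median across targets of the reference CV) so that the
#' dispersion estimate does not collapse with small reference panels.
#' Runs of at least \code{min_consecutive_targets} consecutive targets
#' whose ratio passes the duplication (or deletion) gate with
#' \code{|z| >= z_threshold} are merged into one call. This is an
#' intentionally simple ratio/z caller, not a reimplementation of the
#' published beta-binomial exome-depth model.
#'
#' @param counts list with \code{targets}, \code{case_counts},
#'   \code{reference_matrix} (see \code{\link{simulate_depth_counts}}).
#' @param config \code{\link{consensus_config}}.
#' @return CNV call data.frame with source = "depth".
#' @export
call_cnv_depth <- function(counts, config = consensus_config()) {
  refs <- counts$reference_matrix
  if (is.null(dim(refs)) || ncol(refs) < 2) {
    stop("at least 2 reference samples are required")
  }
  targets <- counts$targets
  case <- counts$case_counts
  stopifnot(length(case) == nrow(targets), nrow(refs) == nrow(targets))
  usable <- rowMeans(refs) > 0
  x <- case / sum(case)
  rn <- sweep(refs, 2, colSums(refs), "/")
  m <- rowMeans(rn)
  s <- apply(rn, 1, stats::sd)
  cv <- stats::median((s / m)[usable], na.rm = TRUE)
  ratio <- ifelse(usable, x / m, NA_real_)
  denom <- cv * m
  z <- ifelse(!usable, NA_real_,
              ifelse(denom > 0, (x - m) / denom,
                     ifelse(x == m, 0, sign(x - m) * Inf)))
  state <- rep("none", nrow(targets))
  state[usable & ratio >= config$ratio_dup & z >= config$z_threshold] <- "dup"
  state[usable & ratio <= config$ratio_del & z <= -config$z_threshold] <- "del"
  runs_to_calls(targets, state, config$min_consecutive_targets)
}

runs_to_calls <- function(targets, state, min_run) {
  grp <- cumsum(c(TRUE, state[-1] != state[-length(state)] |
                    targets$chrom[-1] != targets$chrom[-length(state)]))
  out <- list()
  for (g in split(seq_along(state), grp)) {
    st <- state[g[1]]
    if (st == "none" || length(g) < min_run) next
    out[[length(out) + 1]] <- data.frame(
      chrom = targets$chrom[g[1]],
      start = targets$start[g[1]],
      end = targets$end[g[length(g)]],
      sv_type = st, support = length(g), source = "depth",
      rank = NA_integer_, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sv_type = character(0),
                      support = integer(0), source = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Consensus of the discordant-pair and depth pipelines
#'
#' Emits one consensus call for every pair of calls (one from each
#' pipeline, same chromosome) whose reciprocal overlap reaches the
#' configured threshold. The consensus interval is the intersection; the
#' variant type is kept when both agree and is \code{unknown} otherwise.
#'
#' @param discordant,depth CNV call data.frames.
#' @param config \code{\link{consensus_config}}.
#' @return CNV call data.frame with source = "consensus", sorted by
#'   coordinate.
#' @export
consensus_calls <- function(discordant, depth, config = consensus_config()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sv_type = character(0),
                      support = integer(0), source = character(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (nrow(discordant) == 0 || nrow(depth) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges(discordant), as_granges(depth))
  if (length(hits) == 0) return(empty)
  qa <- S4Vectors::queryHits(hits); sb <- S4Vectors::subjectHits(hits)
  ro <- reciprocal_overlap(discordant[qa, c("chrom", "start", "end")],
                           depth[sb, c("chrom", "start", "end")])
  keep <- ro >= config$reciprocal_overlap
  if (!any(keep)) return(empty)
  qa <- qa[keep]; sb <- sb[keep]
  out <- data.frame(
    chrom = discordant$chrom[qa],
    start = pmax(discordant$start[qa], depth$start[sb]),
    end = pmin(discordant$end[qa], depth$end[sb]),
    sv_type = ifelse(discordant$sv_type[qa] == depth$sv_type[sb],
                     discordant$sv_type[qa], "unknown"),
    support = pmin(discordant$support[qa], depth$support[sb]),
    source = "consensus", rank = NA_integer_, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate CNV calls with overlapping genes
#'
#' A gene is reported when its interval overlaps the call by at least one
#' base; symbols are listed in genomic order, semicolon-separated in the
#' \code{genes} column (empty string when no gene overlaps).
#'
#' @param calls CNV call data.frame.
#' @param gene_intervals data.frame with chrom, start, end, symbol.
#' @return \code{calls} with a \code{genes} column added.
#' @export
annotate_genes <- function(calls, gene_intervals) {
  calls$genes <- rep("", nrow(calls))
  if (nrow(calls) == 0 || nrow(gene_intervals) == 0) return(calls)
  gi <- gene_intervals[order(gene_intervals$chrom, gene_intervals$start), ,
                       drop = FALSE]
  hits <- GenomicRanges::findOverlaps(as_granges(calls), as_granges(gi),
                                      minoverlap = 1L)
  if (length(hits) > 0) {
    by_call <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (q in names(by_call)) {
      calls$genes[as.integer(q)] <-
        paste(gi$symbol[sort(by_call[[q]])], collapse = ";")
    }
  }
  calls
}
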