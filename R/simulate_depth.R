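#' Simulate exon-target read-depth counts for the depth CNV caller
#'
#' Draws negative-binomial counts per target for one case sample and a
#' panel of event-free reference samples. A shared per-target efficiency
#' factor (log-normal) emulates capture bias; the case sample's
#' expectation is multiplied by 1.5 on targets inside a duplication and
#' 0.5 inside a deletion.
#'
#' @param targets interval data.frame, sorted, non-overlapping.
#' @param truth \code{\link{cnv_truth}} rows or NULL.
#' @param mean_depth expected count per target.
#' @param n_reference_samples reference panel size.
#' @param dispersion negative-binomial size parameter (larger = tighter).
#' @param seed integer seed.
#' @return list with \code{counts} (targets + case_count +
#'   reference matrix columns ref1..refK) and \code{manifest}.
#' @export
simulate_depth_counts <- function(targets, truth = NULL, mean_depth = 200,
                                  n_reference_samples = 10L,
                                  dispersion = 200, seed = 1L) {
  o <- order(targets$chrom, targets$start)
  if (!identical(o, seq_len(nrow(targets)))) {
    stop("targets must be sorted by chromosome and start")
  }
  same <- targets$chrom[-1] == targets$chrom[-nrow(targets)]
  if (nrow(targets) > 1 &&
      any(same & targets$start[-1] <= targets$end[-nrow(targets)])) {
    stop("targets must be non-overlapping")
  }
  n <- nrow(targets)
  factor_case <- rep(1, n)
  if (!is.null(truth) && nrow(truth) > 0) {
    tg <- as_granges(targets)
    tr <- as_granges(truth)
    hit <- GenomicRanges::findOverlaps(tg, tr)
    f <- ifelse(truth$sv_type == "tandem_dup", 1.5, 0.5)
    factor_case[S4Vectors::queryHits(hit)] <- f[S4Vectors::subjectHits(hit)]
  }
  with_seed(seed, {
    eff <- exp(stats::rnorm(n, 0, 0.2))   # shared capture-efficiency bias
    mu <- mean_depth * eff
    refs <- vapply(seq_len(n_reference_samples), function(k) {
      stats::rnbinom(n, mu = mu, size = dispersion)
    }, numeric(n))
    colnames(refs) <- sprintf("ref%d", seq_len(n_reference_samples))
    case <- stats::rnbinom(n, mu = mu * factor_case, size = dispersion)
    list(counts = list(targets = targets, case_counts = as.integer(case),
                       reference_matrix = refs),
         manifest = list(truth = if (is.null(truth)) data.frame() else truth,
                         factor_case = factor_case,
                         mean_depth = mean_depth,
                         dispersion = dispersion,
                         n_reference_samples = n_reference_samples,
                         seed = as.integer(seed)))
  })
}

#' Build a regular grid of exon-like targets on one chromosome
#'
#' Convenience for simulations: \code{n} targets of \code{width} bases
#' every \code{gap} bases starting at \code{start}.
#'
#' @param n number of targets.
#' @param chrom chromosome name.
#' @param start first target start.
#' @param width,gap target width and inter-target distance, bases.
#' @return interval data.frame.
#' @export
tile_targets <- function(n, chrom = "chrS", start = 10000L, width = 200L,
                         gap = 2000L) {
  s <- start + (seq_len(n) - 1L) * (width + gap)
  genomic_interval(rep(chrom, n), s, s + width - 1L)
}
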