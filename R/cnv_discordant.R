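#' Configuration of the discordant-pair CNV caller
#'
#' Defaults follow the published in-house pipeline: only reads at the
#' unique-mapping cap (MAPQ exactly 60) with an absolute template length
#' between 2,500 and 350,000 bases (inclusive) are considered, and calls
#' are built from groups of pairs with very similar coordinates (within
#' 5\% at both endpoints). \code{min_support} — the number of supporting
#' templates required before a cluster becomes a call — is not part of
#' the published description; 3 is this package's default and is exposed
#' here.
#'
#' @param mapq_required required mapping quality (equality, not a floor).
#' @param tlen_min,tlen_max inclusive bounds on \code{abs(tlen)}, bases.
#' @param cluster_tolerance endpoint tolerance as a fraction of the mean
#'   span of the two intervals compared.
#' @param min_support minimum templates per reported call.
#' @return a list of class \code{discordant_filter_config}.
#' @export
discordant_config <- function(mapq_required = 60L, tlen_min = 2500L,
                              tlen_max = 350000L, cluster_tolerance = 0.05,
                              min_support = 3L) {
  stopifnot(tlen_min > 0, tlen_min < tlen_max,
            cluster_tolerance > 0, cluster_tolerance < 1, min_support >= 1)
  structure(list(mapq_required = as.integer(mapq_required),
                 tlen_min = as.integer(tlen_min),
                 tlen_max = as.integer(tlen_max),
                 cluster_tolerance = cluster_tolerance,
                 min_support = as.integer(min_support)),
            class = "discordant_filter_config")
}

#' Filter read pairs on mapping quality and template length
#'
#' Retains records with \code{mapq == mapq_required} and
#' \code{tlen_min <= |tlen| <= tlen_max}, keeping exactly one record per
#' template (the leftmost mate, i.e. the positive-TLEN record) so each
#' physical pair is counted once. Records with \code{tlen == 0}
#' (unmapped or single-end mates) are excluded and tallied.
#'
#' @param pairs data.frame from \code{\link{read_sam_pairs}}.
#' @param config \code{\link{discordant_config}}.
#' @return the retained records, with attribute \code{n_skipped_zero_tlen}.
#' @export
filter_discordant_pairs <- function(pairs, config = discordant_config()) {
  stopifnot(all(c("mapq", "tlen") %in% names(pairs)))
  n_zero <- sum(pairs$tlen == 0L)
  keep <- pairs$mapq == config$mapq_required &
    abs(pairs$tlen) >= config$tlen_min &
    abs(pairs$tlen) <= config$tlen_max &
    pairs$tlen > 0L
  out <- pairs[keep, , drop = FALSE]
  out <- out[!duplicated(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_zero_tlen") <- n_zero
  out
}

#' Genomic footprint implied by a discordant pair
#'
#' The interval the template spans on the reference:
#' \code{[pos, pos + |tlen| - 1]}.
#'
#' @param pair data.frame of canonicalized (leftmost-mate) records.
#' @return interval data.frame, one row per record.
#' @export
implied_interval <- function(pair) {
  if (any(abs(pair$tlen) < 1L)) stop("implied_interval: |tlen| must be >= 1")
  genomic_interval(pair$chrom, pair$pos, pair$pos + abs(pair$tlen) - 1L)
}

# Linkage predicate of the clustering step: both endpoints within
# tolerance * mean span of the two intervals compared.
endpoints_link <- function(s1, e1, s2, e2, tolerance) {
  tol <- tolerance * ((e1 - s1 + 1) + (e2 - s2 + 1)) / 2
  abs(s1 - s2) <= tol & abs(e1 - e2) <= tol
}

#' Cluster retained pairs by coordinate similarity
#'
#' Single-linkage clustering of the implied intervals, per chromosome:
#' two intervals link when both their starts and their ends differ by at
#' most \code{cluster_tolerance} of the mean of the two spans. The
#' cluster's representative interval takes the median start and median
#' end of its members. Every retained pair lands in exactly one cluster;
#' singletons are legal.
#'
#' @param retained output of \code{\link{filter_discordant_pairs}}.
#' @param config \code{\link{discordant_config}}.
#' @return data.frame with columns chrom, start, end, support, n_fr,
#'   n_rf, n_other, member_ids (list column).
#' @export
cluster_pairs <- function(retained, config = discordant_config()) {
  if (nrow(retained) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), support = integer(0),
                      n_fr = integer(0), n_rf = integer(0),
                      n_other = integer(0),
                      member_ids = I(list()), stringsAsFactors = FALSE))
  }
  iv <- implied_interval(retained)
  orient <- ifelse(!retained$is_reverse & retained$mate_is_reverse, "FR",
                   ifelse(retained$is_reverse & !retained$mate_is_reverse,
                          "RF", "other"))
  comp <- integer(nrow(iv))
  next_id <- 0L
  for (chr in unique(iv$chrom)) {
    sel <- which(iv$chrom == chr)
    o <- sel[order(iv$start[sel], iv$end[sel])]
    s <- iv$start[o]; e <- iv$end[o]
    parent <- seq_along(o)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    max_reach <- config$cluster_tolerance * config$tlen_max
    for (i in seq_along(o)) {
      j <- i + 1L
      while (j <= length(o) && s[j] - s[i] <= max_reach) {
        if (endpoints_link(s[i], e[i], s[j], e[j], config$cluster_tolerance)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_along(o), find, integer(1))
    comp[o] <- next_id + as.integer(factor(roots))
    next_id <- next_id + length(unique(roots))
  }
  groups <- split(seq_len(nrow(iv)), comp)
  res <- lapply(groups, function(ix) {
    data.frame(
      chrom = iv$chrom[ix[1]],
      start = as.integer(floor(stats::median(iv$start[ix]) + 0.5)),
      end = as.integer(floor(stats::median(iv$end[ix]) + 0.5)),
      support = length(ix),
      n_fr = sum(orient[ix] == "FR"),
      n_rf = sum(orient[ix] == "RF"),
      n_other = sum(orient[ix] == "other"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$member_ids <- I(lapply(groups, function(ix) retained$read_id[ix]))
  rownames(out) <- NULL
  out
}

#' Turn clusters into ranked CNV calls
#'
#' Clusters with at least \code{min_support} members become calls, ranked
#' by support (descending), ties broken by span (descending) then by
#' coordinate. The variant type is taken from the dominant orientation of
#' the members: everted (RF-majority) clusters are duplications,
#' FR-majority clusters deletions, ties \code{unknown}.
#'
#' @param clusters output of \code{\link{cluster_pairs}}.
#' @param config \code{\link{discordant_config}}.
#' @return CNV call data.frame (chrom, start, end, sv_type, support,
#'   source = "discordant", rank).
#' @export
prioritize_clusters <- function(clusters, config = discordant_config()) {
  keep <- clusters$support >= config$min_support
  x <- clusters[keep, , drop = FALSE]
  if (nrow(x) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sv_type = character(0),
                      support = integer(0), source = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  sv <- ifelse(x$n_rf > x$n_fr, "dup", ifelse(x$n_fr > x$n_rf, "del", "unknown"))
  span <- x$end - x$start + 1L
  o <- order(-x$support, -span, x$chrom, x$start)
  out <- data.frame(chrom = x$chrom[o], start = x$start[o], end = x$end[o],
                    sv_type = sv[o], support = x$support[o],
                    source = "discordant", rank = seq_along(o),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' In-house discordant-pair CNV pipeline over a SAM file
#'
#' Composition of \code{\link{read_sam_pairs}},
#' \code{\link{filter_discordant_pairs}}, \code{\link{cluster_pairs}} and
#' \code{\link{prioritize_clusters}}. Deterministic for a fixed input.
#'
#' @param sam SAM/BAM file path.
#' @param config \code{\link{discordant_config}}.
#' @return ranked CNV call data.frame.
#' @examples
#' truth <- cnv_truth(genomic_interval("chrS", 500000, 600000),
#'                    sv_type = "tandem_dup", n_supporting_pairs = 6)
#' sim <- simulate_read_pairs(truth = truth, n_background_pairs = 500, seed = 7)
#' sam <- tempfile(fileext = ".sam")
#' writeLines(sim$sam_lines, sam)
#' call_cnv_discordant(sam)
#' @export
call_cnv_discordant <- function(sam, config = discordant_config()) {
  pairs <- read_sam_pairs(sam)
  retained <- filter_discordant_pairs(pairs, config)
  prioritize_clusters(cluster_pairs(retained, config), config)
}
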