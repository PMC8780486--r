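#' Declare a true copy-number event for the read simulator
#'
#' @param interval single-row interval data.frame.
#' @param sv_type "tandem_dup" or "deletion".
#' @param n_supporting_pairs discordant pairs to emit for the event.
#' @return data.frame of class \code{cnv_truth} (rbind-able).
#' @export
cnv_truth <- function(interval, sv_type = c("tandem_dup", "deletion"),
                      n_supporting_pairs = 6L) {
  sv_type <- match.arg(sv_type)
  data.frame(chrom = interval$chrom, start = interval$start,
             end = interval$end, sv_type = sv_type,
             n_supporting_pairs = as.integer(n_supporting_pairs),
             stringsAsFactors = FALSE)
}

#' Simulate coordinate-sorted paired-end exome alignments with implanted CNVs
#'
#' Emits already-aligned SAM over a toy reference (the caller consumes
#' MAPQ/TLEN/orientation only, so no sequence realignment is performed
#' and SEQ/QUAL are placeholders). Background pairs draw their insert
#' from a positive-truncated Normal in FR orientation at MAPQ 60. Each
#' true event emits \code{n_supporting_pairs} whose implied interval
#' (\code{[pos, pos + |tlen| - 1]}) tracks the true interval to within
#' one read length: tandem duplications as everted (RF) pairs with
#' \code{|tlen|} close to the event span, deletions as FR pairs with
#' \code{|tlen|} close to span + insert. A fraction of low-MAPQ
#' (\code{mapq < 60}) decoy pairs is interleaved. Identical seeds and
#' parameters give byte-identical SAM output.
#'
#' @param reference named integer vector of chromosome lengths.
#' @param truth \code{\link{cnv_truth}} rows (or NULL for event-free).
#' @param normal_insert_mean,normal_insert_sd insert distribution, bases.
#' @param read_length bases per read.
#' @param n_background_pairs concordant pairs to draw.
#' @param decoy_fraction fraction (of background) of low-MAPQ decoys.
#' @param seed integer seed; all randomness flows through it.
#' @return list with \code{records} (a data.frame shaped like
#'   \code{\link{read_sam_pairs}} output, two rows per pair),
#'   \code{sam_lines} (character), and \code{manifest} (truth plus
#'   generator parameters; supporting pairs are guaranteed to pass the
#'   default MAPQ/TLEN filter whenever the event span lies inside the
#'   configured window by at least \code{2 * breakpoint_jitter} bases).
#' @export
simulate_read_pairs <- function(reference = c(chrS = 2000000L), truth = NULL,
                                normal_insert_mean = 300L,
                                normal_insert_sd = 50L, read_length = 150L,
                                n_background_pairs = 5000L,
                                decoy_fraction = 0.01, seed = 1L) {
  jitter_max <- 50L   # per-endpoint placement jitter, bases
  if (!is.null(truth) && nrow(truth) > 0) {
    L <- reference[truth$chrom]
    if (any(is.na(L)) || any(truth$end + read_length + 2L * jitter_max > L) ||
        any(truth$start - read_length - 2L * jitter_max < 1L)) {
      stop("truth interval exceeds the reference (including read margin)")
    }
  }
  with_seed(seed, {
    recs <- list()
    # background: FR proper-like pairs
    if (n_background_pairs > 0) {
      chrom <- sample(names(reference), n_background_pairs, replace = TRUE,
                      prob = as.numeric(reference) / sum(as.numeric(reference)))
      ins <- pmax(read_length + 1L,
                  as.integer(round(stats::rnorm(n_background_pairs,
                                                normal_insert_mean,
                                                normal_insert_sd))))
      maxstart <- reference[chrom] - ins - 1L
      pos <- 1L + as.integer(floor(stats::runif(n_background_pairs) * maxstart))
      recs$bg <- data.frame(read_id = sprintf("bg%06d", seq_len(n_background_pairs)),
                            chrom = chrom, pos = pos, mapq = 60L, tlen = ins,
                            left_rev = FALSE, right_rev = TRUE,
                            stringsAsFactors = FALSE)
    }
    # low-MAPQ decoys: same geometry, mapq < 60
    n_decoy <- as.integer(round(decoy_fraction * n_background_pairs))
    if (n_decoy > 0) {
      chrom <- sample(names(reference), n_decoy, replace = TRUE)
      ins <- sample(500L:100000L, n_decoy, replace = TRUE)
      pos <- 1L + as.integer(floor(stats::runif(n_decoy) *
                                     (reference[chrom] - ins - 1L)))
      recs$decoy <- data.frame(read_id = sprintf("dc%04d", seq_len(n_decoy)),
                               chrom = chrom, pos = pos,
                               mapq = sample(0L:59L, n_decoy, replace = TRUE),
                               tlen = ins, left_rev = FALSE, right_rev = TRUE,
                               stringsAsFactors = FALSE)
    }
    # supporting pairs per true event
    if (!is.null(truth) && nrow(truth) > 0) {
      ev <- lapply(seq_len(nrow(truth)), function(i) {
        n <- truth$n_supporting_pairs[i]
        if (n == 0) return(NULL)
        s <- truth$start[i]; e <- truth$end[i]
        if (truth$sv_type[i] == "tandem_dup") {
          # everted pair inside the event: implied = [s + j1, e + j2]
          j1 <- sample(0:jitter_max, n, replace = TRUE)
          j2 <- -sample(0:jitter_max, n, replace = TRUE)
          pos <- s + j1
          tlen <- (e + j2) - pos + 1L
          lr <- TRUE; rr <- FALSE
        } else {
          # flanking FR pair: implied = [s - read_length + j1, e + read_length + j2]
          j1 <- sample(0:jitter_max, n, replace = TRUE)
          j2 <- -sample(0:jitter_max, n, replace = TRUE)
          pos <- s - read_length + j1
          tlen <- (e + read_length + j2) - pos + 1L
          lr <- FALSE; rr <- TRUE
        }
        data.frame(read_id = sprintf("ev%d_%03d", i, seq_len(n)),
                   chrom = truth$chrom[i], pos = as.integer(pos), mapq = 60L,
                   tlen = as.integer(tlen), left_rev = lr, right_rev = rr,
                   stringsAsFactors = FALSE)
      })
      recs$ev <- do.call(rbind, ev)
    }
    pairs <- do.call(rbind, recs)
    manifest <- list(
      truth = if (is.null(truth)) data.frame() else
        cbind(truth, span = truth$end - truth$start + 1L,
              seed = as.integer(seed)),
      params = list(reference = as.list(reference),
                    normal_insert_mean = normal_insert_mean,
                    normal_insert_sd = normal_insert_sd,
                    read_length = read_length,
                    n_background_pairs = n_background_pairs,
                    decoy_fraction = decoy_fraction,
                    breakpoint_jitter = jitter_max,
                    dup_orientation = "RF", del_orientation = "FR",
                    seed = as.integer(seed))
    )
    if (is.null(pairs) || nrow(pairs) == 0) {
      return(list(records = data.frame(), sam_lines = sam_header(reference),
                  manifest = manifest))
    }
    rownames(pairs) <- NULL
    list(records = pair_records(pairs, read_length),
         sam_lines = render_sam(pairs, reference, read_length),
         manifest = manifest)
  })
}

sam_header <- function(reference) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(reference), as.integer(reference)))
}

# Expand one row per pair into the two mate records, as read_sam_pairs
# would return them.
pair_records <- function(pairs, read_length) {
  right_pos <- pairs$pos + pairs$tlen - read_length
  left <- data.frame(read_id = pairs$read_id, chrom = pairs$chrom,
                     pos = pairs$pos, mapq = pairs$mapq, tlen = pairs$tlen,
                     is_reverse = pairs$left_rev,
                     mate_is_reverse = pairs$right_rev,
                     is_first_in_pair = TRUE, stringsAsFactors = FALSE)
  right <- data.frame(read_id = pairs$read_id, chrom = pairs$chrom,
                      pos = as.integer(right_pos), mapq = pairs$mapq,
                      tlen = -pairs$tlen, is_reverse = pairs$right_rev,
                      mate_is_reverse = pairs$left_rev,
                      is_first_in_pair = FALSE, stringsAsFactors = FALSE)
  out <- rbind(left, right)
  out <- out[order(out$chrom, out$pos, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

render_sam <- function(pairs, reference, read_length) {
  right_pos <- pairs$pos + pairs$tlen - read_length
  flag_left <- 1L + 64L + ifelse(pairs$left_rev, 16L, 0L) +
    ifelse(pairs$right_rev, 32L, 0L)
  flag_right <- 1L + 128L + ifelse(pairs$right_rev, 16L, 0L) +
    ifelse(pairs$left_rev, 32L, 0L)
  cigar <- sprintf("%dM", read_length)
  line <- function(id, flag, chrom, pos, mapq, mpos, tlen) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
            id, flag, chrom, pos, mapq, cigar, mpos, tlen)
  }
  lines <- c(line(pairs$read_id, flag_left, pairs$chrom, pairs$pos,
                  pairs$mapq, as.integer(right_pos), pairs$tlen),
             line(pairs$read_id, flag_right, pairs$chrom,
                  as.integer(right_pos), pairs$mapq, pairs$pos, -pairs$tlen))
  pos_all <- c(pairs$pos, as.integer(right_pos))
  chrom_all <- c(pairs$chrom, pairs$chrom)
  id_all <- c(pairs$read_id, pairs$read_id)
  o <- order(match(chrom_all, names(reference)), pos_all, id_all)
  c(sam_header(reference), lines[o])
}
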