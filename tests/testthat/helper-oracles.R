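# Independent oracles and small utilities shared across the test files.

# Brute-force single-linkage oracle: build the full pairwise linkage
# matrix (both endpoints within tolerance * mean span, same chromosome)
# and take its transitive closure by boolean fixpoint iteration.
# Returns an integer component label per interval.
oracle_single_linkage <- function(iv, tolerance) {
  n <- nrow(iv)
  if (n == 0) return(integer(0))
  span <- iv$end - iv$start + 1
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tol <- tolerance * (span[i] + span[j]) / 2
      link[i, j] <- iv$chrom[i] == iv$chrom[j] &&
        abs(iv$start[i] - iv$start[j]) <= tol &&
        abs(iv$end[i] - iv$end[j]) <= tol
    }
  }
  repeat {
    nxt <- link | ((link %*% link) > 0)
    if (identical(nxt, link)) break
    link <- nxt
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[link[i, ]] <- next_id
    }
  }
  comp
}

# canonical form of a partition given per-element labels: sorted list of
# sorted member index vectors, for label-agnostic comparison
canonical_partition <- function(labels) {
  g <- unname(split(seq_along(labels), labels))
  g <- lapply(g, sort)
  g[order(vapply(g, `[[`, integer(1), 1L))]
}

# synthetic retained-pair records (already passing the default filter)
random_retained_records <- function(n, seed, chrom = "chrS") {
  set.seed(seed)
  tlen <- sample(2500:350000, n, replace = TRUE)
  data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    chrom = chrom,
    pos = sample.int(1500000L, n, replace = TRUE),
    mapq = 60L,
    tlen = tlen,
    is_reverse = sample(c(TRUE, FALSE), n, replace = TRUE),
    mate_is_reverse = sample(c(TRUE, FALSE), n, replace = TRUE),
    is_first_in_pair = TRUE,
    stringsAsFactors = FALSE
  )
}

# discordant pipeline over in-memory records (no SAM round trip)
call_cnv_from_records <- function(records, config = discordant_config()) {
  prioritize_clusters(cluster_pairs(filter_discordant_pairs(records, config),
                                    config), config)
}

write_temp_lines <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# best reciprocal overlap between any call and a single truth interval
best_truth_overlap <- function(calls, truth_iv) {
  if (nrow(calls) == 0) return(0)
  max(reciprocal_overlap(calls[, c("chrom", "start", "end")],
                         truth_iv[rep(1, nrow(calls)), , drop = FALSE]))
}
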