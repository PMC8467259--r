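#' Levenshtein edit distance
#'
#' Unit-cost edit distance (insertions, deletions, substitutions) computed by
#' bottom-up dynamic programming. This is the distance used for fuzzy
#' matching of observed window insertions against the expected donor
#' insertion; high per-base error rates make exact matching useless for long
#' reads.
#'
#' @param a,b Character scalars.
#' @return Integer edit distance.
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  cur <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur[1L] <- i
    xi <- x[i]
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,          # deletion
                         cur[j] + 1L,                # insertion
                         prev[j] + (xi != y[j]))     # substitution
    }
    tmp <- prev; prev <- cur; cur <- tmp
  }
  as.integer(prev[m + 1L])
}

#' Maximum edit distance accepted for a GT-positive call
#'
#' A window insertion counts as the expected donor insertion when its
#' Levenshtein distance is at most one third of the modification size,
#' rounded down: 6 edits for an 18 bp insertion, 1 edit for a 3 bp insertion,
#' and 0 (exact match) for insertions shorter than 3 bp.
#'
#' @param insertion_length Length of the expected donor insertion in bp.
#' @return Integer threshold, `floor(insertion_length / 3)`.
#' @export
gt_threshold <- function(insertion_length) {
  insertion_length <- as.integer(insertion_length)
  if (is.na(insertion_length) || insertion_length < 1L) {
    stop("gtamp_bad_length: insertion_length must be a positive integer",
         call. = FALSE)
  }
  insertion_length %/% 3L
}

#' Classify reads as GT-positive or GT-negative
#'
#' For each read, all insertions anchored in the target window are merged (in
#' read order) into one candidate insertion; the read is GT-positive when the
#' candidate's Levenshtein distance to the expected donor insertion is within
#' the threshold from [gt_threshold()]. The edit distance is reported for
#' every read that has a candidate, whether or not it passes.
#'
#' @param reads Alignment `data.frame` from [load_alignments()].
#' @param locus A `reference_locus`.
#' @param spec A `donor_spec` for the same locus.
#' @return `data.frame` with one row per read: `read_id`, `sample_id`,
#'   `is_gt`, `observed_insertion` (`NA` when none), `edit_distance` (`NA`
#'   when no candidate), `threshold`.
#' @export
classify_reads <- function(reads, locus, spec) {
  expected <- spec$insertion_sequence
  thr <- gt_threshold(nchar(expected))
  n <- nrow(reads)
  obs <- character(n); dist <- rep(NA_integer_, n); is_gt <- logical(n)
  for (i in seq_len(n)) {
    rd <- list(read_id = reads$read_id[i], ref_start = reads$ref_start[i],
               cigar = reads$cigar[i], seq = reads$seq[i])
    cand <- merge_window_insertions(extract_window_variants(rd, locus))
    obs[i] <- cand
    if (!is.na(cand)) {
      dist[i] <- levenshtein(cand, expected)
      is_gt[i] <- dist[i] <= thr
    }
  }
  data.frame(
    read_id = reads$read_id,
    sample_id = reads$sample_id,
    is_gt = is_gt,
    observed_insertion = obs,
    edit_distance = dist,
    threshold = thr,
    stringsAsFactors = FALSE
  )
}

#' Classify a single read
#'
#' Convenience wrapper around [classify_reads()] for one alignment record.
#'
#' @inheritParams classify_reads
#' @param read One row of the alignment `data.frame`.
#' @return A one-row `data.frame` as in [classify_reads()].
#' @export
classify_read <- function(read, locus, spec) {
  classify_reads(read, locus, spec)
}
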