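# Independent oracles and fixture builders shared across the suite.

# Naive exponential-time edit distance by direct recursion over edit scripts.
# Used only on short strings; deliberately independent of the package's
# dynamic-programming implementation.
naive_lev <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  ra <- substr(a, 2L, nchar(a))
  rb <- substr(b, 2L, nchar(b))
  cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  min(naive_lev(ra, b) + 1L, naive_lev(a, rb) + 1L, naive_lev(ra, rb) + cost)
}

# Top-down memoised recursion (independent route from the bottom-up DP).
memo_lev <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- as.integer(substr(a, i, i) != substr(b, j, j))
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L, rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# All DNA strings of length 0..max_len.
all_dna_upto <- function(max_len) {
  out <- ""
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), l))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# Brute-force interval-overlap oracle: does the deletion [start, start+len)
# touch the closed window [w1, w2]?
del_overlaps_window <- function(start, len, w) {
  length(intersect(start:(start + len - 1L), w[1]:w[2])) > 0L
}

# Write a minimal single-reference SAM file from a record data.frame with
# columns qname, flag, pos (1-based), mapq, cigar, seq.
write_test_sam <- function(path, ref_name, ref_len, records,
                           sample_id = "test") {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len),
    sprintf("@RG\tID:%s\tSM:%s", sample_id, sample_id)
  )
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$qname, r$flag, if (bitwAnd(r$flag, 4L) != 0L) "*" else ref_name,
          r$pos, r$mapq, r$cigar, "*", 0L, 0L, r$seq, "*", sep = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  path
}

# A fixed 1 kb locus (deterministic) used by hand-constructed read tests.
fixed_locus <- function(cut_site = 500L, window_halfwidth = 4L, len = 1000L,
                        seed = 424242L) {
  withr::with_seed(seed, {
    reference_locus(
      name = "fixref",
      sequence = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = ""),
      cut_site = cut_site,
      window_halfwidth = window_halfwidth
    )
  })
}

# Build an aligned-read record (as a one-row data.frame) whose query is
# derived from the locus by the given CIGAR, with insertions filled by
# `ins_seq` in order.
read_from_cigar <- function(locus, ref_start, cigar, ins_seq = "",
                            read_id = "r1", sample_id = "test") {
  ops <- gregexpr("\\d+[MIDS]", cigar)[[1]]
  toks <- regmatches(cigar, list(ops))[[1]]
  n <- nchar(toks)
  op <- substr(toks, n, n)
  len <- as.integer(substr(toks, 1, n - 1))
  ref <- ref_start
  qparts <- character(0)
  ins_cursor <- 0L
  for (i in seq_along(op)) {
    if (op[i] %in% c("M")) {
      qparts <- c(qparts, substr(locus$sequence, ref + 1L, ref + len[i]))
      ref <- ref + len[i]
    } else if (op[i] == "I") {
      qparts <- c(qparts,
                  substr(ins_seq, ins_cursor + 1L, ins_cursor + len[i]))
      ins_cursor <- ins_cursor + len[i]
    } else if (op[i] == "D") {
      ref <- ref + len[i]
    } else if (op[i] == "S") {
      qparts <- c(qparts, strrep("A", len[i]))
    }
  }
  data.frame(read_id = read_id, sample_id = sample_id,
             ref_start = ref_start, mapq = 60L, cigar = cigar,
             seq = paste(qparts, collapse = ""), stringsAsFactors = FALSE)
}

# Minimal donor_spec stub for arm-level smoothing tests: `arms` is a
# character vector ("left"/"right") in catalog order with distances assigned
# outward per arm.
spec_stub <- function(arms, spacing = 10L) {
  n <- length(arms)
  distance <- integer(n)
  left_idx <- which(arms == "left")
  right_idx <- which(arms == "right")
  # catalog order is by ref_pos: left arm outermost first
  distance[left_idx] <- -rev(seq_len(length(left_idx))) * spacing
  distance[right_idx] <- seq_len(length(right_idx)) * spacing
  structure(list(
    insertion_sequence = "ACGTACGTACGTACGTAC",
    insertion_position = 500L,
    snps = data.frame(
      ref_pos = 500L + distance, ref_base = rep("A", n),
      donor_base = rep("G", n), arm = arms, distance = distance,
      stringsAsFactors = FALSE
    )
  ), class = "donor_spec")
}

snp_vec <- function(states, read_id = "r1") {
  structure(list(read_id = read_id, states = states,
                 partial_coverage = FALSE), class = "snp_vector")
}

# Variant-table stub for subtraction tests.
vt_stub <- function(keys, total_reads, sample_id = "s",
                    locus_name = "fixref", cut_site = 500L,
                    window_halfwidth = 4L) {
  tab <- if (is.null(keys)) {
    data.frame(vtype = character(0), ref_pos = integer(0),
               length = integer(0), count = integer(0))
  } else keys
  tab$frequency_pct <- 100 * tab$count / total_reads
  structure(list(
    sample_id = sample_id, total_reads = total_reads,
    reads_with_variant_pct = NA_real_, locus_name = locus_name,
    cut_site = cut_site, window_halfwidth = window_halfwidth, table = tab
  ), class = "variant_table")
}
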