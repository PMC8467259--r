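#' Extract indel variants inside the target window from one read
#'
#' Walks the read's CIGAR with reference and query cursors and emits every
#' insertion and deletion that touches the indel target window around the
#' cut site. An insertion is anchored at the reference position before which
#' its bases sit and intersects the window when that anchor lies in the
#' closed window; a deletion intersects when `[start, start + length)`
#' overlaps the window.
#'
#' @param read One row of the alignment `data.frame` from
#'   [load_alignments()] (or any list with `ref_start`, `cigar`, `seq`).
#' @param locus A `reference_locus`.
#' @return `data.frame` with columns `vtype` ("insertion"/"deletion"),
#'   `ref_pos` (0-based), `length`, `sequence` (inserted bases; `""` for
#'   deletions), in read order. Zero rows when the window is clean.
#' @export
extract_window_variants <- function(read, locus) {
  w <- locus_window(locus)
  ops <- parse_cigar(read$cigar)
  if (cigar_query_length(ops) != nchar(read$seq)) {
    stop("gtamp_malformed_cigar: query length disagrees with CIGAR for read ",
         read$read_id %||% "<unnamed>", call. = FALSE)
  }
  ref <- as.integer(read$ref_start)
  q <- 0L
  out_type <- character(0); out_pos <- integer(0)
  out_len <- integer(0); out_seq <- character(0)
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      ref <- ref + len; q <- q + len
    } else if (op == "I") {
      if (ref >= w[1] && ref <= w[2]) {
        out_type <- c(out_type, "insertion"); out_pos <- c(out_pos, ref)
        out_len <- c(out_len, len)
        out_seq <- c(out_seq, substr(read$seq, q + 1L, q + len))
      }
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (ref <= w[2] && (ref + len - 1L) >= w[1]) {
        out_type <- c(out_type, "deletion"); out_pos <- c(out_pos, ref)
        out_len <- c(out_len, len)
        out_seq <- c(out_seq, "")
      }
      ref <- ref + len
    } else if (op == "S") {
      q <- q + len
    } # H, P consume nothing
  }
  data.frame(vtype = out_type, ref_pos = out_pos, length = out_len,
             sequence = out_seq, stringsAsFactors = FALSE)
}

#' Merge a read's window insertions into one candidate insertion
#'
#' Long insertions in high-error long reads are often split by the aligner
#' into several nearby `I` operations. The candidate sequence compared against
#' the expected donor insertion is the concatenation, in read order, of all
#' insertions anchored inside the target window.
#'
#' @param variants Output of [extract_window_variants()] for a single read.
#' @return A single character string, or `NA_character_` when the read has no
#'   window insertion.
#' @export
merge_window_insertions <- function(variants) {
  ins <- variants$sequence[variants$vtype == "insertion"]
  if (length(ins) == 0L) return(NA_character_)
  paste(ins, collapse = "")
}

#' Tabulate window indel variants across a sample's reads
#'
#' Builds the per-sample variant frequency table used by the
#' background-subtraction step. Variants are keyed by (type, position,
#' length) — not by inserted sequence, which per-base errors would fragment —
#' and each read contributes at most one count per distinct key.
#'
#' @param reads Alignment `data.frame` from [load_alignments()].
#' @param locus A `reference_locus`.
#' @param exclude_read_ids Read ids to drop before tabulation (e.g.
#'   GT-positive reads, which are a separate outcome from mutagenesis).
#' @return An object of class `variant_table`: list with `sample_id`,
#'   `total_reads`, `reads_with_variant_pct`, `locus_name`, `cut_site`,
#'   `window_halfwidth`, and `table`, a `data.frame` with `vtype`, `ref_pos`,
#'   `length`, `count`, `frequency_pct` sorted by decreasing frequency.
#' @export
tabulate_variants <- function(reads, locus, exclude_read_ids = NULL) {
  if (!is.null(exclude_read_ids)) {
    reads <- reads[!reads$read_id %in% exclude_read_ids, , drop = FALSE]
  }
  n <- nrow(reads)
  if (n == 0L) {
    stop("gtamp_empty_input: no reads to tabulate", call. = FALSE)
  }
  keys_by_read <- vector("list", n)
  for (i in seq_len(n)) {
    rd <- list(read_id = reads$read_id[i], ref_start = reads$ref_start[i],
               cigar = reads$cigar[i], seq = reads$seq[i])
    v <- extract_window_variants(rd, locus)
    if (nrow(v)) {
      keys_by_read[[i]] <- unique(paste(v$vtype, v$ref_pos, v$length, sep = ":"))
    }
  }
  n_with <- sum(lengths(keys_by_read) > 0L)
  all_keys <- unlist(keys_by_read, use.names = FALSE)
  tab <- if (length(all_keys)) {
    counts <- sort(table(all_keys), decreasing = TRUE)
    parts <- strsplit(names(counts), ":", fixed = TRUE)
    data.frame(
      vtype = vapply(parts, `[`, "", 1L),
      ref_pos = as.integer(vapply(parts, `[`, "", 2L)),
      length = as.integer(vapply(parts, `[`, "", 3L)),
      count = as.integer(counts),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(vtype = character(0), ref_pos = integer(0), length = integer(0),
               count = integer(0), stringsAsFactors = FALSE)
  }
  tab$frequency_pct <- 100 * tab$count / n
  structure(
    list(
      sample_id = reads$sample_id[1] %||% NA_character_,
      total_reads = n,
      reads_with_variant_pct = 100 * n_with / n,
      locus_name = locus$name,
      cut_site = locus$cut_site,
      window_halfwidth = locus$window_halfwidth,
      table = tab
    ),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(
    "<variant_table> %s: %d reads, %.2f%% with a window variant, %d distinct keys\n",
    x$sample_id, x$total_reads, x$reads_with_variant_pct, nrow(x$table)))
  invisible(x)
}

#' Background-subtracted targeted-mutagenesis frequency
#'
#' Subtracts, key by key, the variant frequencies observed in a no-nuclease
#' control from those of a treated sample; the sum of the positive
#' differences above `threshold_pct` is the adjusted targeted-mutagenesis
#' frequency. With no control the raw treated frequencies are thresholded
#' directly, with a warning.
#'
#' @param treated `variant_table` for the treated sample.
#' @param control `variant_table` for the matched no-nuclease control, or
#'   `NULL`.
#' @param threshold_pct Post-subtraction frequency (percent) a variant must
#'   exceed to contribute (default 0.5).
#' @return An object of class `mutagenesis_result`: list with `sample_id`,
#'   `total_reads`, `raw_variant_read_fraction` (percent of reads with >= 1
#'   window variant), `adjusted_frequency` (percent), `control_used`, and
#'   `contributing_variants`, a `data.frame` of the keys that contribute with
#'   treated/control/subtracted frequencies.
#' @export
subtract_background <- function(treated, control = NULL, threshold_pct = 0.5) {
  stopifnot(inherits(treated, "variant_table"))
  if (!is.null(control)) {
    stopifnot(inherits(control, "variant_table"))
    same <- identical(treated$locus_name, control$locus_name) &&
      identical(treated$cut_site, control$cut_site) &&
      identical(treated$window_halfwidth, control$window_halfwidth)
    if (!same) {
      stop("gtamp_locus_mismatch: treated and control variant tables were ",
           "built against different loci/windows", call. = FALSE)
    }
  } else {
    warning("no control sample supplied: adjusted frequency is the sum of raw ",
            "treated variant frequencies above the threshold, without ",
            "background subtraction")
  }
  tt <- treated$table
  key <- paste(tt$vtype, tt$ref_pos, tt$length, sep = ":")
  ctrl_freq <- rep(0, nrow(tt))
  if (!is.null(control) && nrow(control$table)) {
    ct <- control$table
    ckey <- paste(ct$vtype, ct$ref_pos, ct$length, sep = ":")
    m <- match(key, ckey)
    ctrl_freq[!is.na(m)] <- ct$frequency_pct[m[!is.na(m)]]
  }
  diff <- tt$frequency_pct - ctrl_freq
  contributes <- diff > threshold_pct
  contributing <- data.frame(
    vtype = tt$vtype, ref_pos = tt$ref_pos, length = tt$length,
    treated_pct = tt$frequency_pct, control_pct = ctrl_freq,
    subtracted_pct = diff, stringsAsFactors = FALSE
  )[contributes, , drop = FALSE]
  rownames(contributing) <- NULL
  structure(
    list(
      sample_id = treated$sample_id,
      total_reads = treated$total_reads,
      raw_variant_read_fraction = treated$reads_with_variant_pct,
      adjusted_frequency = sum(contributing$subtracted_pct),
      threshold_pct = threshold_pct,
      control_used = !is.null(control),
      contributing_variants = contributing
    ),
    class = "mutagenesis_result"
  )
}

#' @export
print.mutagenesis_result <- function(x, ...) {
  cat(sprintf(
    "<mutagenesis_result> %s: %.2f%% reads with window variant; adjusted targeted mutagenesis %.2f%% (%d contributing variants%s)\n",
    x$sample_id, x$raw_variant_read_fraction, x$adjusted_frequency,
    nrow(x$contributing_variants),
    if (x$control_used) "" else "; NO CONTROL SUBTRACTED"))
  invisible(x)
}
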