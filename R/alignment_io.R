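#' Load an amplicon reference locus from FASTA
#'
#' Reads the reference amplicon sequence and attaches the predicted nuclease
#' cut site and the indel target window. All coordinates in the package are
#' 0-based; the target window is the closed interval
#' `[cut_site - window_halfwidth, cut_site + window_halfwidth]`, clipped to
#' the sequence bounds.
#'
#' @param path Path to a FASTA file. The first record is used; a warning is
#'   issued if the file contains more than one record.
#' @param cut_site Integer, 0-based offset of the predicted cut position in
#'   the reference sequence.
#' @param window_halfwidth Integer half-width (bp) of the indel target window
#'   around the cut site (default 4).
#' @return An object of class `reference_locus`: a list with elements `name`,
#'   `sequence` (uppercase), `cut_site`, and `window_halfwidth`.
#' @export
load_reference <- function(path, cut_site, window_halfwidth = 4L) {
  if (!file.exists(path)) {
    stop("gtamp_missing_file: reference FASTA not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("gtamp_empty_fasta: no records in ", path, call. = FALSE)
  }
  if (length(seqs) > 1L) {
    warning("reference FASTA has ", length(seqs), " records; using the first")
  }
  reference_locus(
    name = sub("\\s.*$", "", names(seqs)[1]),
    sequence = toupper(as.character(seqs[[1]])),
    cut_site = cut_site,
    window_halfwidth = window_halfwidth
  )
}

#' Construct a reference locus
#'
#' @param name Sequence name (must match the SAM header of alignments
#'   analyzed against this locus).
#' @param sequence Uppercase DNA string (A/C/G/T/N).
#' @param cut_site 0-based predicted cut position.
#' @param window_halfwidth Half-width of the indel target window in bp.
#' @return A `reference_locus` object.
#' @export
reference_locus <- function(name, sequence, cut_site, window_halfwidth = 4L) {
  sequence <- toupper(sequence)
  cut_site <- as.integer(cut_site)
  window_halfwidth <- as.integer(window_halfwidth)
  if (grepl("[^ACGTN]", sequence)) {
    stop("gtamp_bad_sequence: reference contains non-ACGTN characters",
         call. = FALSE)
  }
  if (is.na(cut_site) || cut_site < 0L || cut_site >= nchar(sequence)) {
    stop("gtamp_cut_site_out_of_bounds: cut_site ", cut_site,
         " outside [0, ", nchar(sequence) - 1L, "]", call. = FALSE)
  }
  if (window_halfwidth < 0L) {
    stop("gtamp_bad_window: window_halfwidth must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, cut_site = cut_site,
         window_halfwidth = window_halfwidth),
    class = "reference_locus"
  )
}

#' @export
print.reference_locus <- function(x, ...) {
  w <- locus_window(x)
  cat(sprintf("<reference_locus> %s: %d bp, cut site %d, window [%d, %d]\n",
              x$name, nchar(x$sequence), x$cut_site, w[1], w[2]))
  invisible(x)
}

#' Target window of a locus
#'
#' @param locus A `reference_locus`.
#' @return Integer vector `c(start, end)`, the closed 0-based window, clipped
#'   to the sequence bounds.
#' @export
locus_window <- function(locus) {
  c(max(0L, locus$cut_site - locus$window_halfwidth),
    min(nchar(locus$sequence) - 1L, locus$cut_site + locus$window_halfwidth))
}

#' Load aligned amplicon reads from SAM/BAM
#'
#' Reads a SAM or BAM file and returns the mapped, primary, non-supplementary
#' alignments with mapping quality at or above `min_mapq`. SAM's 1-based POS
#' is converted to a 0-based `ref_start` here, exactly once; all downstream
#' coordinates are 0-based. The number of records excluded by each filter is
#' recorded in the `filter_counts` attribute so every denominator can be
#' audited.
#'
#' @param path SAM or BAM file. The header must name the locus: a mismatch
#'   between the `@SQ` sequence name and `locus$name` is a hard error.
#' @param locus A `reference_locus` the reads were aligned to.
#' @param sample_id Sample label; defaults to the `SM` field of the first
#'   `@RG` header line, falling back to the file basename.
#' @param min_mapq Minimum mapping quality (default 1, excluding only
#'   mapq-0 multimappers).
#' @return A `data.frame` with columns `read_id`, `sample_id`, `ref_start`
#'   (0-based), `mapq`, `cigar`, `seq`, carrying attributes `filter_counts`
#'   (named integer vector: `total`, `unmapped`, `secondary`,
#'   `supplementary`, `low_mapq`, `yielded`) and `locus_name`.
#' @export
load_alignments <- function(path, locus, sample_id = NULL, min_mapq = 1L) {
  if (!file.exists(path)) {
    stop("gtamp_missing_file: alignment file not found: ", path, call. = FALSE)
  }
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  targets <- names(hdr$targets)
  if (!locus$name %in% targets) {
    stop("gtamp_locus_mismatch: SAM header targets [",
         paste(targets, collapse = ", "), "] do not include locus '",
         locus$name, "'", call. = FALSE)
  }
  if (is.null(sample_id)) {
    rg <- hdr$text[names(hdr$text) == "@RG"]
    sm <- unlist(lapply(rg, function(f) sub("^SM:", "", f[grepl("^SM:", f)])))
    sample_id <- if (length(unique(sm)) == 1L) sm[[1]] else
      sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  n_total <- length(flag)
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- !unmapped & bitwAnd(flag, 256L) != 0L
  supplementary <- !unmapped & !secondary & bitwAnd(flag, 2048L) != 0L
  low_mapq <- !unmapped & !secondary & !supplementary & res$mapq < min_mapq
  keep <- !(unmapped | secondary | supplementary | low_mapq)

  reads <- data.frame(
    read_id = res$qname[keep],
    sample_id = rep(sample_id, sum(keep)),
    ref_start = res$pos[keep] - 1L,
    mapq = res$mapq[keep],
    cigar = res$cigar[keep],
    seq = as.character(res$seq[keep]),
    stringsAsFactors = FALSE
  )
  # CIGAR / query-length consistency check on the kept records
  bad <- vapply(seq_len(nrow(reads)), function(i) {
    ops <- parse_cigar(reads$cigar[i])
    cigar_query_length(ops) != nchar(reads$seq[i])
  }, logical(1))
  if (any(bad)) {
    stop("gtamp_malformed_cigar: query length disagrees with CIGAR for read(s) ",
         paste(utils::head(reads$read_id[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  attr(reads, "filter_counts") <- c(
    total = n_total,
    unmapped = sum(unmapped),
    secondary = sum(secondary),
    supplementary = sum(supplementary),
    low_mapq = sum(low_mapq),
    yielded = sum(keep)
  )
  attr(reads, "locus_name") <- locus$name
  reads
}
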