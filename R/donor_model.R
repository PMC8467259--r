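#' Derive the donor specification from donor and reference sequences
#'
#' Aligns the donor to the reference amplicon (global in the donor, local in
#' the reference) and decomposes it into two homology arms flanking a single
#' donor-only insertion, cataloging every arm mismatch as a donor SNP. The
#' insertion is left-aligned, as in standard variant normalization, so its
#' coordinate is deterministic even when flanking bases make several
#' placements equivalent.
#'
#' SNP `distance` is the signed bp offset from the insertion point as drawn
#' on conversion-tract plots: for a SNP left of the insertion it is
#' `ref_pos - insertion_position` (negative); for a SNP to the right it is
#' `ref_pos - insertion_position + 1`, so that the innermost possible
#' positions on the two arms are -1 and +1 and |distance| is symmetric.
#'
#' @param donor Donor DNA string, or a `DNAString`/`DNAStringSet` of length 1.
#' @param locus A `reference_locus`.
#' @param match,mismatch,gap_opening,gap_extension Alignment scores for the
#'   donor-to-reference alignment (defaults +1/-1/4/1; the gap penalties are
#'   costs, i.e. subtracted).
#' @return An object of class `donor_spec`: list with `donor_sequence`,
#'   `insertion_sequence`, `insertion_position` (0-based reference coordinate
#'   before which the insertion sits), `left_arm_span` and `right_arm_span`
#'   (0-based half-open reference intervals), and `snps`, a `data.frame` with
#'   columns `ref_pos`, `ref_base`, `donor_base`, `arm` ("left"/"right"),
#'   `distance`, sorted by `ref_pos`.
#' @export
build_donor_spec <- function(donor, locus, match = 1, mismatch = -1,
                             gap_opening = 4, gap_extension = 1) {
  donor <- toupper(as.character(donor)[1])
  if (grepl("[^ACGTN]", donor)) {
    stop("gtamp_bad_sequence: donor contains non-ACGTN characters", call. = FALSE)
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = donor, subject = locus$sequence,
    type = "global-local", substitutionMatrix = submat,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  dch <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  rch <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_offset <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based

  ref_cursor <- ref_offset
  ins_runs <- list()          # each: list(pos, seq)
  cur_ins <- NULL
  snp_pos <- integer(0); snp_ref <- character(0); snp_donor <- character(0)
  for (i in seq_along(dch)) {
    if (rch[i] == "-") {                      # donor-only base
      if (is.null(cur_ins)) cur_ins <- list(pos = ref_cursor, seq = dch[i])
      else cur_ins$seq <- paste0(cur_ins$seq, dch[i])
    } else {
      if (!is.null(cur_ins)) { ins_runs[[length(ins_runs) + 1L]] <- cur_ins; cur_ins <- NULL }
      if (dch[i] == "-") {
        stop("gtamp_donor_deletion: donor-to-reference alignment contains a ",
             "reference-only segment at position ", ref_cursor,
             "; donors encoding deletions are not supported", call. = FALSE)
      }
      if (dch[i] != rch[i]) {
        snp_pos <- c(snp_pos, ref_cursor)
        snp_ref <- c(snp_ref, rch[i])
        snp_donor <- c(snp_donor, dch[i])
      }
      ref_cursor <- ref_cursor + 1L
    }
  }
  if (!is.null(cur_ins)) ins_runs[[length(ins_runs) + 1L]] <- cur_ins
  if (length(ins_runs) != 1L) {
    stop("gtamp_ambiguous_insertion: expected exactly one contiguous ",
         "donor-only insertion, found ", length(ins_runs),
         if (length(ins_runs) > 1)
           paste0(" (at reference positions ",
                  paste(vapply(ins_runs, `[[`, 0, "pos"), collapse = ", "), ")"),
         call. = FALSE)
  }
  ins_pos <- ins_runs[[1]]$pos
  ins_seq <- ins_runs[[1]]$seq

  # Left-align the insertion: while the reference base before the insertion
  # equals the last inserted base, rotate the insertion one position left.
  ref_chars <- strsplit(locus$sequence, "")[[1]]
  while (ins_pos > ref_offset &&
         ref_chars[ins_pos] == substr(ins_seq, nchar(ins_seq), nchar(ins_seq)) &&
         !(ins_pos - 1L) %in% snp_pos) {
    ins_seq <- paste0(substr(ins_seq, nchar(ins_seq), nchar(ins_seq)),
                      substr(ins_seq, 1L, nchar(ins_seq) - 1L))
    ins_pos <- ins_pos - 1L
  }

  if (ins_pos != locus$cut_site) {
    warning("donor insertion position (", ins_pos,
            ") differs from the locus cut site (", locus$cut_site, ")")
  }

  arm_start <- ref_offset
  arm_end <- ref_cursor                      # half-open end of homology
  distance <- ifelse(snp_pos < ins_pos, snp_pos - ins_pos, snp_pos - ins_pos + 1L)
  snps <- data.frame(
    ref_pos = snp_pos,
    ref_base = snp_ref,
    donor_base = snp_donor,
    arm = ifelse(snp_pos < ins_pos, "left", "right"),
    distance = as.integer(distance),
    stringsAsFactors = FALSE
  )
  snps <- snps[order(snps$ref_pos), , drop = FALSE]
  rownames(snps) <- NULL

  structure(
    list(
      donor_sequence = donor,
      insertion_sequence = ins_seq,
      insertion_position = as.integer(ins_pos),
      left_arm_span = c(arm_start, as.integer(ins_pos)),
      right_arm_span = c(as.integer(ins_pos), arm_end),
      snps = snps
    ),
    class = "donor_spec"
  )
}

#' @export
print.donor_spec <- function(x, ...) {
  cat(sprintf(
    "<donor_spec> %d bp insertion at ref pos %d; arms [%d,%d) / [%d,%d); %d SNPs\n",
    nchar(x$insertion_sequence), x$insertion_position,
    x$left_arm_span[1], x$left_arm_span[2],
    x$right_arm_span[1], x$right_arm_span[2], nrow(x$snps)))
  invisible(x)
}

#' Donor SNPs that fall inside the indel target window
#'
#' Tract SNPs whose position collides with the indel target window cannot be
#' scored independently of the insertion itself; this helper identifies them.
#'
#' @param spec A `donor_spec`.
#' @param locus The `reference_locus` the spec was built against.
#' @return The subset of `spec$snps` with `|distance| <= window_halfwidth`.
#' @export
snps_inside_window <- function(spec, locus) {
  spec$snps[abs(spec$snps$distance) <= locus$window_halfwidth, , drop = FALSE]
}

#' Serialize a donor spec to JSON
#'
#' Writes a human-readable sidecar (insertion, arm spans, SNP catalog) for
#' audit alongside pipeline outputs.
#'
#' @param spec A `donor_spec`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_donor_spec <- function(spec, path) {
  jsonlite::write_json(
    list(
      insertion_sequence = spec$insertion_sequence,
      insertion_position = spec$insertion_position,
      left_arm_span = spec$left_arm_span,
      right_arm_span = spec$right_arm_span,
      snps = spec$snps
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
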