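# Query bases aligned to given 0-based reference positions, via a CIGAR walk.
# Returns a character vector parallel to `positions`; NA where the position is
# deleted, clipped, or not covered by the alignment.
aligned_bases_at <- function(read, positions) {
  ops <- parse_cigar(read$cigar)
  out <- rep(NA_character_, length(positions))
  ref <- as.integer(read$ref_start)
  q <- 0L
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      hit <- which(positions >= ref & positions < ref + len)
      if (length(hit)) {
        off <- positions[hit] - ref
        out[hit] <- substring(read$seq, q + off + 1L, q + off + 1L)
      }
      ref <- ref + len; q <- q + len
    } else if (op == "I") {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    } else if (op == "S") {
      q <- q + len
    }
  }
  out
}

#' Mark donor-SNP states along a read
#'
#' For each cataloged donor SNP, locates the read base aligned to the SNP's
#' reference position and scores it `DONOR` when it equals the donor base and
#' `WT` otherwise. A third base, a deleted base, or an uncovered position all
#' score `WT`: states are strictly binary, and interior miscalls are later
#' rescued by the fill-in smoothing step.
#'
#' @param read One row of the alignment `data.frame` (normally a GT-positive
#'   read).
#' @param spec A `donor_spec` with at least one SNP.
#' @param locus The `reference_locus`.
#' @return An object of class `snp_vector`: list with `read_id`, `states`
#'   (character, `"DONOR"`/`"WT"`, in catalog order, i.e. by reference
#'   position), and `partial_coverage` (TRUE when the alignment does not span
#'   the full SNP catalog).
#' @export
mark_snp_states <- function(read, spec, locus) {
  if (nrow(spec$snps) == 0L) {
    stop("gtamp_no_snps: donor spec has an empty SNP catalog", call. = FALSE)
  }
  bases <- aligned_bases_at(read, spec$snps$ref_pos)
  structure(
    list(
      read_id = read$read_id %||% NA_character_,
      states = ifelse(!is.na(bases) & toupper(bases) == spec$snps$donor_base,
                      "DONOR", "WT"),
      partial_coverage = anyNA(bases)
    ),
    class = "snp_vector"
  )
}

# Smooth one arm's states, ordered OUTWARD from the insertion.
# Step 1 (truncation): scanning outward, find the first run of `run_length`
# consecutive WT states; every state strictly beyond that run is set WT.
# Step 2 (fill-in): every state inside the tract delimited by the outermost
# remaining DONOR state is set DONOR.
smooth_arm <- function(donor_logical, run_length) {
  n <- length(donor_logical)
  if (n == 0L) return(donor_logical)
  count <- 0L
  for (i in seq_len(n)) {
    count <- if (donor_logical[i]) 0L else count + 1L
    if (count == run_length) {
      if (i < n) donor_logical[(i + 1L):n] <- FALSE
      break
    }
  }
  outer <- if (any(donor_logical)) max(which(donor_logical)) else 0L
  if (outer > 1L) donor_logical[seq_len(outer)] <- TRUE
  donor_logical
}

#' Apply error-smoothing rules to a read's SNP states
#'
#' Per-base sequencing error both creates spurious `DONOR` calls far from the
#' insertion and punches spurious `WT` holes inside genuine conversion
#' tracts. Two rules, applied per arm scanning outward from the insertion,
#' mitigate both: any SNP external to `run_length` consecutive WT SNPs is
#' ignored (set WT), and WT positions remaining inside the putative tract —
#' the region bounded by the outermost surviving DONOR state — are filled in
#' as DONOR. The result is always a contiguous tract anchored at the
#' insertion, and the operation is idempotent.
#'
#' @param vec A `snp_vector` from [mark_snp_states()].
#' @param spec The `donor_spec` the vector was marked against (defines arm
#'   membership and outward order).
#' @param run_length Number of consecutive WT SNPs that terminates a tract
#'   (default 3).
#' @return A smoothed `snp_vector`.
#' @export
smooth_states <- function(vec, spec, run_length = 3L) {
  run_length <- as.integer(run_length)
  if (is.na(run_length) || run_length < 1L) {
    stop("gtamp_bad_run_length: run_length must be >= 1", call. = FALSE)
  }
  donor <- vec$states == "DONOR"
  left <- which(spec$snps$arm == "left")
  right <- which(spec$snps$arm == "right")
  # left arm outward = decreasing reference position (reverse catalog order)
  lo <- rev(left)
  donor[lo] <- smooth_arm(donor[lo], run_length)
  donor[right] <- smooth_arm(donor[right], run_length)
  vec$states <- ifelse(donor, "DONOR", "WT")
  vec
}

#' Conversion-tract extent of a read
#'
#' The per-arm extent is the |distance| (bp from the insertion) of the
#' outermost SNP in `DONOR` state, or 0 when the arm incorporated no donor
#' SNP — the quantity plotted on two-dimensional tract heatmaps.
#'
#' @param vec A (smoothed) `snp_vector`.
#' @param spec The corresponding `donor_spec`.
#' @return `data.frame` with `read_id`, `left_extent`, `right_extent` (bp).
#' @export
tract_extent <- function(vec, spec) {
  donor <- vec$states == "DONOR"
  ext <- function(arm) {
    idx <- which(spec$snps$arm == arm & donor)
    if (length(idx)) max(abs(spec$snps$distance[idx])) else 0L
  }
  data.frame(read_id = vec$read_id,
             left_extent = ext("left"), right_extent = ext("right"),
             stringsAsFactors = FALSE)
}

#' Summarize conversion tracts across GT reads
#'
#' Computes, after smoothing, the percentage of GT reads that incorporated
#' each donor SNP, the per-read (left, right) tract extents, and the
#' two-dimensional extent count table used for hexbin-style heatmaps.
#'
#' @param vectors List of smoothed `snp_vector`s (one per GT read).
#' @param spec The `donor_spec`.
#' @return An object of class `tract_summary`: list with `per_snp`
#'   (`data.frame`: `ref_pos`, `arm`, `distance`, `n_donor`,
#'   `pct_incorporated`), `extents` (per-read `data.frame`), `hexbin`
#'   (`data.frame`: `left_extent`, `right_extent`, `count`), and
#'   `n_gt_reads`.
#' @export
summarize_tracts <- function(vectors, spec) {
  if (length(vectors) == 0L) {
    stop("gtamp_empty_input: no GT reads to summarize", call. = FALSE)
  }
  mat <- vapply(vectors, function(v) v$states == "DONOR",
                logical(nrow(spec$snps)))
  mat <- matrix(mat, nrow = nrow(spec$snps))   # snps x reads
  n <- length(vectors)
  per_snp <- data.frame(
    ref_pos = spec$snps$ref_pos,
    arm = spec$snps$arm,
    distance = spec$snps$distance,
    n_donor = as.integer(rowSums(mat)),
    stringsAsFactors = FALSE
  )
  per_snp$pct_incorporated <- 100 * per_snp$n_donor / n
  extents <- do.call(rbind, lapply(vectors, tract_extent, spec = spec))
  hex <- as.data.frame(table(left_extent = extents$left_extent,
                             right_extent = extents$right_extent),
                       stringsAsFactors = FALSE)
  names(hex)[3] <- "count"
  hex$left_extent <- as.integer(hex$left_extent)
  hex$right_extent <- as.integer(hex$right_extent)
  hex <- hex[hex$count > 0, , drop = FALSE]
  rownames(hex) <- NULL
  structure(
    list(per_snp = per_snp, extents = extents, hexbin = hex, n_gt_reads = n),
    class = "tract_summary"
  )
}

#' @export
print.tract_summary <- function(x, ...) {
  cat(sprintf(
    "<tract_summary> %d GT reads, %d SNPs; median extents L=%d R=%d bp\n",
    x$n_gt_reads, nrow(x$per_snp),
    as.integer(stats::median(x$extents$left_extent)),
    as.integer(stats::median(x$extents$right_extent))))
  invisible(x)
}
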