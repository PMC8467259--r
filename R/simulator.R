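#' Simulation configuration
#'
#' Bundles the parameters of the synthetic amplicon experiment: locus/donor
#' geometry (500 bp homology arms, insertion at a centered cut site,
#' optionally engineered SNPs at a fixed spacing), the composition of the
#' read population, the conversion-tract length model, and a nanopore-style
#' i.i.d. per-base error process.
#'
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   outputs.
#' @param n_reads Number of reads to simulate.
#' @param gt_fraction Proportion of reads that are gene-targeting events
#'   (carry the donor insertion and a per-arm SNP tract).
#' @param indel_background_fraction Proportion of reads given a random
#'   (non-GT) indel of 1-20 bp anchored in the target window, emulating
#'   targeted mutagenesis.
#' @param mutagenesis_spectrum Number of distinct characteristic indels the
#'   background-indel reads are drawn from (default 1). Cas9 repair outcomes
#'   at a given cut are dominated by a small set of recurrent indels; reads
#'   in the background-indel class each carry one variant sampled from this
#'   per-sample spectrum. Set to `0` for a fully random indel per read.
#' @param insertion_length Length (bp) of the donor insertion (3 or 18
#'   typical; default 18).
#' @param arm_length Homology arm length in bp (default 500).
#' @param snp_spacing Spacing of engineered donor SNPs in bp (30 or 50
#'   typical), or `NA` for a SNP-free donor.
#' @param tract_p Parameter of the per-arm geometric tract model: the number
#'   of consecutive innermost SNPs incorporated on each arm of a GT read is
#'   drawn independently per arm as a geometric variable with success
#'   probability `tract_p`, truncated at the number of SNPs per arm
#'   (default 0.5). Ignored for SNP-free donors.
#' @param error_sub,error_ins,error_del Per-base substitution / insertion /
#'   deletion error probabilities (defaults 0.03/0.03/0.04, approximating
#'   R9.4.1 single-read accuracy). Each insertion event inserts a run of
#'   geometric length (mean 4/3).
#' @param flank Reference bases outside each homology arm (default 50), so
#'   the donor aligns strictly inside the amplicon.
#' @param sample_id Sample label written to the SAM read group.
#' @param truncate_fraction Proportion of reads truncated to a random prefix/
#'   suffix of the amplicon, to exercise partial-coverage handling
#'   (default 0).
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(seed = 1L, n_reads = 1000L, gt_fraction = 0,
                       indel_background_fraction = 0,
                       mutagenesis_spectrum = 1L,
                       insertion_length = 18L, arm_length = 500L,
                       snp_spacing = NA_integer_, tract_p = 0.5,
                       error_sub = 0.03, error_ins = 0.03, error_del = 0.04,
                       flank = 50L, sample_id = "sim",
                       truncate_fraction = 0) {
  cfg <- list(
    seed = as.integer(seed), n_reads = as.integer(n_reads),
    gt_fraction = gt_fraction,
    indel_background_fraction = indel_background_fraction,
    mutagenesis_spectrum = as.integer(mutagenesis_spectrum),
    insertion_length = as.integer(insertion_length),
    arm_length = as.integer(arm_length),
    snp_spacing = as.integer(snp_spacing), tract_p = tract_p,
    error_sub = error_sub, error_ins = error_ins, error_del = error_del,
    flank = as.integer(flank), sample_id = sample_id,
    truncate_fraction = truncate_fraction
  )
  with(cfg, {
    stopifnot(
      n_reads >= 1L, insertion_length >= 1L, arm_length >= 1L, flank >= 0L,
      gt_fraction >= 0, gt_fraction <= 1,
      indel_background_fraction >= 0, indel_background_fraction <= 1,
      gt_fraction + indel_background_fraction <= 1,
      error_sub >= 0, error_sub < 1, error_ins >= 0, error_ins < 1,
      error_del >= 0, error_del < 1,
      tract_p > 0, tract_p <= 1,
      truncate_fraction >= 0, truncate_fraction <= 1
    )
    if (!is.na(snp_spacing) && snp_spacing > arm_length) {
      stop("gtamp_bad_geometry: snp_spacing exceeds arm_length", call. = FALSE)
    }
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic reference locus and donor
#'
#' Draws a random reference amplicon of `2 * arm_length + 2 * flank` bp with
#' the cut site at its center and derives the donor: the two homology arms
#' with the insertion placed at the cut site and, when `snp_spacing` is set,
#' donor SNPs substituted every `snp_spacing` bp outward from the insertion
#' on both arms (positions colliding with the indel target window are
#' skipped). Deterministic under `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @param window_halfwidth Target-window half-width passed to the locus
#'   (default 4).
#' @return List with `locus` (a `reference_locus`), `donor` (DNA string), and
#'   `truth_snps` (`data.frame` of engineered SNP positions/bases).
#' @export
make_locus_and_donor <- function(cfg, window_halfwidth = 4L) {
  set.seed(cfg$seed)
  L <- 2L * cfg$arm_length + 2L * cfg$flank
  ref <- sample(DNA_BASES, L, replace = TRUE)
  cut <- cfg$flank + cfg$arm_length            # 0-based, center
  locus <- reference_locus(
    name = sprintf("amplicon_%dbp", L),
    sequence = paste(ref, collapse = ""),
    cut_site = cut,
    window_halfwidth = window_halfwidth
  )
  insertion <- sample(DNA_BASES, cfg$insertion_length, replace = TRUE)
  # Avoid insertion/flank ambiguity so the donor spec's left-aligned
  # placement coincides with the cut site: the first inserted base must
  # differ from the reference base entering the site, and the last from the
  # base before it.
  if (insertion[1] == ref[cut + 1L]) {
    insertion[1] <- sample(setdiff(DNA_BASES, ref[cut + 1L]), 1L)
  }
  if (insertion[length(insertion)] == ref[cut]) {
    insertion[length(insertion)] <- sample(setdiff(DNA_BASES, ref[cut]), 1L)
  }

  larm <- ref[(cut - cfg$arm_length + 1L):cut]           # 1-based slice
  rarm <- ref[(cut + 1L):(cut + cfg$arm_length)]
  truth_snps <- data.frame(ref_pos = integer(0), ref_base = character(0),
                           donor_base = character(0), arm = character(0),
                           distance = integer(0), stringsAsFactors = FALSE)
  if (!is.na(cfg$snp_spacing)) {
    dists <- seq(cfg$snp_spacing, cfg$arm_length, by = cfg$snp_spacing)
    dists <- dists[dists > window_halfwidth]
    for (d in dists) {
      # left arm: |distance| d -> ref_pos = cut - d (0-based)
      p <- cut - d
      nb <- sample(setdiff(DNA_BASES, ref[p + 1L]), 1L)
      larm[cfg$arm_length - d + 1L] <- nb
      truth_snps <- rbind(truth_snps, data.frame(
        ref_pos = p, ref_base = ref[p + 1L], donor_base = nb,
        arm = "left", distance = -d, stringsAsFactors = FALSE))
      # right arm: |distance| d -> ref_pos = cut + d - 1 (0-based)
      p <- cut + d - 1L
      nb <- sample(setdiff(DNA_BASES, ref[p + 1L]), 1L)
      rarm[d] <- nb
      truth_snps <- rbind(truth_snps, data.frame(
        ref_pos = p, ref_base = ref[p + 1L], donor_base = nb,
        arm = "right", distance = d, stringsAsFactors = FALSE))
    }
    truth_snps <- truth_snps[order(truth_snps$ref_pos), , drop = FALSE]
    rownames(truth_snps) <- NULL
  }
  donor <- paste(c(larm, insertion, rarm), collapse = "")
  list(locus = locus, donor = donor, truth_snps = truth_snps)
}

# Apply the i.i.d. per-base error process to one read, represented as
# alignment columns. `op`: integer vector (1=M, 2=I, 3=D) over alignment
# columns; `base`: integer base codes (1..4) for query-consuming columns (NA
# for D). Returns the updated columns.
apply_errors <- function(op, base, p_sub, p_ins, p_del) {
  qcols <- which(op != 3L)
  nq <- length(qcols)
  if (nq == 0L) return(list(op = op, base = base))
  u_del <- stats::runif(nq) < p_del
  u_sub <- stats::runif(nq) < p_sub
  u_ins <- stats::runif(nq) < p_ins

  # substitutions first (they do not apply to bases that get deleted)
  sub_at <- qcols[u_sub & !u_del]
  if (length(sub_at)) {
    shift <- sample.int(3L, length(sub_at), replace = TRUE)
    base[sub_at] <- (base[sub_at] - 1L + shift) %% 4L + 1L
  }
  # insertion runs: geometric length, continuation probability 0.25
  ins_at <- qcols[u_ins]
  ins_pos <- numeric(0); ins_base <- integer(0)
  if (length(ins_at)) {
    runs <- 1L + stats::rgeom(length(ins_at), prob = 0.75)
    ins_pos <- rep(ins_at + 0.5, runs)
    ins_base <- sample.int(4L, sum(runs), replace = TRUE)
  }
  # deletions: an M column loses its query base (becomes D); an I column
  # disappears entirely
  del_at <- qcols[u_del]
  drop <- del_at[op[del_at] == 2L]
  to_D <- del_at[op[del_at] == 1L]
  op[to_D] <- 3L
  base[to_D] <- NA_integer_

  pos <- seq_along(op)
  keep <- setdiff(pos, drop)
  all_pos <- c(pos[keep], ins_pos)
  all_op <- c(op[keep], rep(2L, length(ins_pos)))
  all_base <- c(base[keep], ins_base)
  ord <- order(all_pos)
  list(op = all_op[ord], base = all_base[ord])
}

# Run-length encode alignment columns into a CIGAR string, trimming leading/
# trailing deletions (and adjusting ref_start for leading ones).
columns_to_record <- function(op, base, ref_start = 0L) {
  # trim flanking deletions
  qcol <- op != 3L
  if (!any(qcol)) return(NULL)
  first <- which(qcol)[1]
  last <- max(which(qcol))
  if (first > 1L) ref_start <- ref_start + sum(op[seq_len(first - 1L)] == 3L)
  op <- op[first:last]; base <- base[first:last]
  r <- rle(c("M", "I", "D")[op])
  list(
    cigar = paste0(r$lengths, r$values, collapse = ""),
    seq = paste(DNA_BASES[base[op != 3L]], collapse = ""),
    ref_start = as.integer(ref_start)
  )
}

#' Simulate aligned amplicon reads with ground truth
#'
#' Generates `cfg$n_reads` reads spanning the full amplicon. Each read is
#' wild-type, gene-targeting (donor insertion at the cut site plus a per-arm
#' SNP tract drawn from the geometric tract model), or background-indel (one
#' characteristic 1-20 bp indel anchored in the target window), with
#' per-base errors applied on top. CIGARs are computed from the true edit
#' script, so no external aligner is involved, and the emitted SAM passes the
#' package's own consistency checks. Deterministic under `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @param sim Output of [make_locus_and_donor()] for the same config.
#' @param dir Output directory (created if needed).
#' @param basename Stem for output files (default `cfg$sample_id`).
#' @return List with paths `sam`, `truth`, `reference_fasta`, `donor_fasta`,
#'   `config_json` and the `truth` `data.frame` (columns `read_id`, `class`,
#'   `is_gt`, `true_left_extent`, `true_right_extent`,
#'   `has_background_indel`).
#' @export
simulate_reads <- function(cfg, sim, dir, basename = cfg$sample_id) {
  set.seed(cfg$seed + 1L)
  locus <- sim$locus
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- nchar(locus$sequence)
  cut <- locus$cut_site
  ref_codes <- match(strsplit(locus$sequence, "")[[1]], DNA_BASES)
  w <- locus_window(locus)
  snps <- sim$truth_snps
  n_snp_arm <- if (nrow(snps)) sum(snps$arm == "left") else 0L

  # per-sample characteristic mutagenesis spectrum
  spectrum <- NULL
  if (cfg$mutagenesis_spectrum > 0L && cfg$indel_background_fraction > 0) {
    spectrum <- data.frame(
      vtype = sample(c("deletion", "insertion"), cfg$mutagenesis_spectrum,
                     replace = TRUE, prob = c(0.6, 0.4)),
      anchor = sample(w[1]:w[2], cfg$mutagenesis_spectrum, replace = TRUE),
      length = pmin(1L + stats::rgeom(cfg$mutagenesis_spectrum, 0.6), 20L),
      stringsAsFactors = FALSE
    )
  }

  u <- stats::runif(cfg$n_reads)
  class <- ifelse(u < cfg$gt_fraction, "gt",
                  ifelse(u < cfg$gt_fraction + cfg$indel_background_fraction,
                         "indel", "wt"))
  ins_codes <- NULL
  gt_idx <- which(class == "gt")
  if (length(gt_idx)) {
    spec_for_sim <- build_donor_spec(sim$donor, locus)
    ins_codes <- match(strsplit(spec_for_sim$insertion_sequence, "")[[1]],
                       DNA_BASES)
  }
  # per-arm tract draws (number of innermost SNPs incorporated)
  k_left <- k_right <- integer(cfg$n_reads)
  if (length(gt_idx) && n_snp_arm > 0L) {
    k_left[gt_idx] <- pmin(stats::rgeom(length(gt_idx), cfg$tract_p), n_snp_arm)
    k_right[gt_idx] <- pmin(stats::rgeom(length(gt_idx), cfg$tract_p), n_snp_arm)
  }
  snp_left <- snps[snps$arm == "left", , drop = FALSE]
  snp_left <- snp_left[order(-snp_left$ref_pos), , drop = FALSE]   # inner first
  snp_right <- snps[snps$arm == "right", , drop = FALSE]           # inner first
  donor_codes_left <- match(snp_left$donor_base, DNA_BASES)
  donor_codes_right <- match(snp_right$donor_base, DNA_BASES)

  records <- vector("list", cfg$n_reads)
  truth <- data.frame(
    read_id = sprintf("read%06d", seq_len(cfg$n_reads)),
    class = class,
    is_gt = class == "gt",
    true_left_extent = 0L, true_right_extent = 0L,
    has_background_indel = class == "indel",
    stringsAsFactors = FALSE
  )

  for (i in seq_len(cfg$n_reads)) {
    base <- ref_codes
    op <- rep(1L, L)
    if (class[i] == "gt") {
      if (k_left[i] > 0L) {
        idx <- seq_len(k_left[i])
        base[snp_left$ref_pos[idx] + 1L] <- donor_codes_left[idx]
        truth$true_left_extent[i] <- abs(snp_left$distance[k_left[i]])
      }
      if (k_right[i] > 0L) {
        idx <- seq_len(k_right[i])
        base[snp_right$ref_pos[idx] + 1L] <- donor_codes_right[idx]
        truth$true_right_extent[i] <- snp_right$distance[k_right[i]]
      }
      # splice the insertion columns before 0-based position `cut`
      base <- c(base[seq_len(cut)], ins_codes, base[(cut + 1L):L])
      op <- c(op[seq_len(cut)], rep(2L, length(ins_codes)), op[(cut + 1L):L])
    } else if (class[i] == "indel") {
      v <- if (!is.null(spectrum)) {
        spectrum[sample.int(nrow(spectrum), 1L), ]
      } else {
        data.frame(vtype = sample(c("deletion", "insertion"), 1L),
                   anchor = sample(w[1]:w[2], 1L),
                   length = sample.int(20L, 1L), stringsAsFactors = FALSE)
      }
      if (v$vtype == "insertion") {
        newb <- sample.int(4L, v$length, replace = TRUE)
        base <- c(base[seq_len(v$anchor)], newb, base[(v$anchor + 1L):L])
        op <- c(op[seq_len(v$anchor)], rep(2L, v$length), op[(v$anchor + 1L):L])
      } else {
        span <- v$anchor:min(v$anchor + v$length - 1L, L - 1L)
        op[span + 1L] <- 3L
        base[span + 1L] <- NA_integer_
      }
    }
    cols <- apply_errors(op, base, cfg$error_sub, cfg$error_ins, cfg$error_del)
    op2 <- cols$op; base2 <- cols$base
    ref_start <- 0L
    if (cfg$truncate_fraction > 0 && stats::runif(1L) < cfg$truncate_fraction) {
      # keep a random prefix or suffix covering >= 40% of the alignment
      ncol2 <- length(op2)
      keep <- max(2L, as.integer(ncol2 * stats::runif(1L, 0.4, 0.9)))
      if (stats::runif(1L) < 0.5) {
        drop_ref <- sum(op2[seq_len(ncol2 - keep)] == 3L) +
          sum(op2[seq_len(ncol2 - keep)] == 1L)
        ref_start <- ref_start + drop_ref
        op2 <- op2[(ncol2 - keep + 1L):ncol2]
        base2 <- base2[(ncol2 - keep + 1L):ncol2]
      } else {
        op2 <- op2[seq_len(keep)]
        base2 <- base2[seq_len(keep)]
      }
    }
    records[[i]] <- columns_to_record(op2, base2, ref_start)
  }

  ok <- !vapply(records, is.null, logical(1))
  records <- records[ok]
  truth <- truth[ok, , drop = FALSE]
  lines <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    paste(truth$read_id[i], "0", locus$name, r$ref_start + 1L, "60",
          r$cigar, "*", "0", "0", r$seq, "*",
          paste0("RG:Z:", cfg$sample_id), sep = "\t")
  }, character(1))
  ord <- order(vapply(records, `[[`, 0L, "ref_start"))
  lines <- lines[ord]

  paths <- list(
    sam = file.path(dir, paste0(basename, ".sam")),
    truth = file.path(dir, paste0(basename, ".truth.tsv")),
    reference_fasta = file.path(dir, paste0(basename, ".reference.fasta")),
    donor_fasta = file.path(dir, paste0(basename, ".donor.fasta")),
    config_json = file.path(dir, paste0(basename, ".config.json"))
  )
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", locus$name, L),
    sprintf("@RG\tID:%s\tSM:%s", cfg$sample_id, cfg$sample_id),
    "@PG\tID:gtamp\tPN:gtamp"
  )
  writeLines(c(header, lines), paths$sam)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(sprintf(">%s", locus$name), locus$sequence),
             paths$reference_fasta)
  writeLines(c(sprintf(">%s_donor", locus$name), sim$donor),
             paths$donor_fasta)
  jsonlite::write_json(unclass(cfg), paths$config_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(paths, list(truth_table = truth))
}
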