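#' Pipeline run configuration
#'
#' Collects the inputs and the method parameters shared by the three
#' analyses. The defaults are the method's published operating point: a
#' +/- 4 bp indel target window, a 0.5% post-subtraction variant-frequency
#' threshold, a Levenshtein acceptance radius of 1/3 of the modification
#' size, and tract smoothing terminated by 3 consecutive WT SNPs.
#'
#' @param reference_path Reference amplicon FASTA.
#' @param cut_site 0-based predicted cut position in the reference.
#' @param donor_path Donor FASTA (optional for mutagenesis-only runs).
#' @param samples Named character vector: `sample_id = path` to SAM/BAM.
#' @param control Sample id of the no-nuclease control among `samples`, or
#'   `NA`.
#' @param window_halfwidth Indel window half-width in bp (default 4).
#' @param freq_threshold_pct Post-subtraction variant-frequency threshold in
#'   percent (default 0.5).
#' @param ld_fraction Fraction of the modification size used as the
#'   Levenshtein acceptance radius (default 1/3; rounded down).
#' @param wt_run_length Consecutive-WT run length terminating a conversion
#'   tract (default 3).
#' @param min_mapq Minimum mapping quality (default 1).
#' @param out_dir Output directory.
#' @param include_gt_in_mutagenesis Keep GT-positive reads in the mutagenesis
#'   variant table (default FALSE: GT and mutagenesis are separate outcomes).
#' @param exclude_partial_coverage Drop GT reads whose alignment does not
#'   span the full SNP catalog from tract analysis (default FALSE; they are
#'   flagged either way).
#' @param plot Also render tract plots (requires ggplot2; default FALSE).
#' @return A `run_config` object.
#' @export
run_config <- function(reference_path, cut_site, donor_path = NA_character_,
                       samples = character(0), control = NA_character_,
                       window_halfwidth = 4L, freq_threshold_pct = 0.5,
                       ld_fraction = 1 / 3, wt_run_length = 3L, min_mapq = 1L,
                       out_dir = ".", include_gt_in_mutagenesis = FALSE,
                       exclude_partial_coverage = FALSE, plot = FALSE) {
  if (abs(ld_fraction - 1 / 3) > 1e-9) {
    warning("ld_fraction differs from the published 1/3 rule; ",
            "thresholds will not match the published anchors")
  }
  structure(
    list(reference_path = reference_path, cut_site = as.integer(cut_site),
         donor_path = donor_path, samples = samples, control = control,
         window_halfwidth = as.integer(window_halfwidth),
         freq_threshold_pct = freq_threshold_pct, ld_fraction = ld_fraction,
         wt_run_length = as.integer(wt_run_length),
         min_mapq = as.integer(min_mapq), out_dir = out_dir,
         include_gt_in_mutagenesis = include_gt_in_mutagenesis,
         exclude_partial_coverage = exclude_partial_coverage, plot = plot),
    class = "run_config"
  )
}

log_msg <- function(...) message(sprintf(...))

load_cfg_inputs <- function(cfg, need_donor = FALSE) {
  locus <- load_reference(cfg$reference_path, cfg$cut_site,
                          cfg$window_halfwidth)
  spec <- NULL
  if (!is.na(cfg$donor_path)) {
    donor <- Biostrings::readDNAStringSet(cfg$donor_path)
    if (length(donor) == 0L) {
      stop("gtamp_empty_fasta: no records in ", cfg$donor_path, call. = FALSE)
    }
    spec <- build_donor_spec(as.character(donor[[1]]), locus)
  } else if (need_donor) {
    stop("gtamp_missing_donor: this analysis requires a donor FASTA",
         call. = FALSE)
  }
  if (length(cfg$samples) == 0L) {
    stop("gtamp_missing_inputs: no sample alignments supplied", call. = FALSE)
  }
  reads <- lapply(names(cfg$samples), function(sid) {
    r <- load_alignments(cfg$samples[[sid]], locus, sample_id = sid,
                         min_mapq = cfg$min_mapq)
    fc <- attr(r, "filter_counts")
    log_msg("[%s] %d records: %d yielded, %d unmapped, %d secondary, %d supplementary, %d low-mapq",
            sid, fc["total"], fc["yielded"], fc["unmapped"], fc["secondary"],
            fc["supplementary"], fc["low_mapq"])
    if (nrow(r) == 0L) {
      stop("gtamp_empty_input: no usable alignments in ", cfg$samples[[sid]],
           call. = FALSE)
    }
    r
  })
  names(reads) <- names(cfg$samples)
  list(locus = locus, spec = spec, reads = reads)
}

#' Run the targeted-mutagenesis analysis
#'
#' Tabulates window indel variants for every sample, subtracts the control
#' sample's variant frequencies key by key, and writes the per-variant and
#' per-sample summary tables. GT-positive reads are excluded from the
#' variant tables unless `include_gt_in_mutagenesis` is set (a donor must be
#' supplied for the exclusion to be possible).
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list of `mutagenesis_result` objects (one per
#'   treated sample). Writes `mutagenesis_variants.tsv` and
#'   `mutagenesis_summary.tsv` under `cfg$out_dir`.
#' @export
run_mutagenesis <- function(cfg) {
  inp <- load_cfg_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- lapply(names(inp$reads), function(sid) {
    excl <- NULL
    if (!is.null(inp$spec) && !cfg$include_gt_in_mutagenesis) {
      calls <- classify_reads(inp$reads[[sid]], inp$locus, inp$spec)
      excl <- calls$read_id[calls$is_gt]
      log_msg("[%s] %d GT-positive reads excluded from mutagenesis table",
              sid, length(excl))
    }
    tabulate_variants(inp$reads[[sid]], inp$locus, exclude_read_ids = excl)
  })
  names(tables) <- names(inp$reads)
  ctrl <- if (!is.na(cfg$control)) {
    if (!cfg$control %in% names(tables)) {
      stop("gtamp_missing_inputs: control sample '", cfg$control,
           "' not among the supplied samples", call. = FALSE)
    }
    tables[[cfg$control]]
  } else NULL
  treated_ids <- setdiff(names(tables), cfg$control)
  results <- lapply(treated_ids, function(sid) {
    subtract_background(tables[[sid]], ctrl,
                        threshold_pct = cfg$freq_threshold_pct)
  })
  names(results) <- treated_ids

  var_rows <- do.call(rbind, lapply(treated_ids, function(sid) {
    tt <- tables[[sid]]$table
    if (nrow(tt) == 0L) return(NULL)
    key <- paste(tt$vtype, tt$ref_pos, tt$length, sep = ":")
    ctrl_freq <- rep(0, nrow(tt))
    if (!is.null(ctrl) && nrow(ctrl$table)) {
      ckey <- paste(ctrl$table$vtype, ctrl$table$ref_pos, ctrl$table$length,
                    sep = ":")
      m <- match(key, ckey)
      ctrl_freq[!is.na(m)] <- ctrl$table$frequency_pct[m[!is.na(m)]]
    }
    diff <- tt$frequency_pct - ctrl_freq
    data.frame(sample_id = sid, vtype = tt$vtype, ref_pos = tt$ref_pos,
               length = tt$length, count = tt$count,
               frequency_pct = tt$frequency_pct,
               control_frequency_pct = ctrl_freq, subtracted_pct = diff,
               contributes = ifelse(diff > cfg$freq_threshold_pct, "yes", "no"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(var_rows)) {
    var_rows <- data.frame(sample_id = character(0), vtype = character(0),
                           ref_pos = integer(0), length = integer(0),
                           count = integer(0), frequency_pct = numeric(0),
                           control_frequency_pct = numeric(0),
                           subtracted_pct = numeric(0),
                           contributes = character(0))
  }
  summary_rows <- do.call(rbind, lapply(treated_ids, function(sid) {
    r <- results[[sid]]
    data.frame(sample_id = sid, total_reads = r$total_reads,
               reads_with_variant_pct = r$raw_variant_read_fraction,
               adjusted_frequency_pct = r$adjusted_frequency,
               control_used = r$control_used, stringsAsFactors = FALSE)
  }))
  cfg_list <- unclass(cfg)
  write_tsv_with_header(var_rows,
                        file.path(cfg$out_dir, "mutagenesis_variants.tsv"),
                        cfg_list)
  write_tsv_with_header(summary_rows,
                        file.path(cfg$out_dir, "mutagenesis_summary.tsv"),
                        cfg_list)
  invisible(results)
}

#' Run the gene-targeting analysis
#'
#' Classifies every read of every sample as GT-positive or negative by fuzzy
#' matching of window insertions against the expected donor insertion, and
#' writes per-read calls plus a per-sample summary.
#'
#' @param cfg A `run_config` (donor required).
#' @return Invisibly, a list with `calls` (per-read `data.frame`) and
#'   `summary` (per-sample `data.frame` with `gt_reads`, `total_reads`,
#'   `gt_pct`). Writes `gt_calls.tsv` and `gt_summary.tsv` under
#'   `cfg$out_dir`.
#' @export
run_gt <- function(cfg) {
  inp <- load_cfg_inputs(cfg, need_donor = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- do.call(rbind, lapply(names(inp$reads), function(sid) {
    cl <- classify_reads(inp$reads[[sid]], inp$locus, inp$spec)
    log_msg("[%s] %d / %d reads GT-positive", sid, sum(cl$is_gt), nrow(cl))
    cl
  }))
  summary_rows <- do.call(rbind, lapply(split(calls, calls$sample_id),
                                        function(d) {
    data.frame(sample_id = d$sample_id[1], gt_reads = sum(d$is_gt),
               total_reads = nrow(d), gt_pct = 100 * mean(d$is_gt),
               stringsAsFactors = FALSE)
  }))
  rownames(summary_rows) <- NULL
  cfg_list <- unclass(cfg)
  write_tsv_with_header(calls, file.path(cfg$out_dir, "gt_calls.tsv"),
                        cfg_list)
  write_tsv_with_header(summary_rows,
                        file.path(cfg$out_dir, "gt_summary.tsv"), cfg_list)
  invisible(list(calls = calls, summary = summary_rows))
}

#' Run the conversion-tract analysis
#'
#' For each sample's GT-positive reads, phases donor-SNP incorporation,
#' applies the smoothing rules, and writes the per-SNP incorporation table,
#' the per-read extent table, and the two-dimensional extent count matrix.
#'
#' @param cfg A `run_config` (donor with at least one SNP required).
#' @return Invisibly, a named list of `tract_summary` objects per sample
#'   (samples with zero GT reads are skipped with a message). Writes
#'   `tract_snp_freq.tsv`, `tract_extents.tsv` and `tract_hexbin.tsv` under
#'   `cfg$out_dir`, and `tract_plots.pdf` when `cfg$plot` is TRUE.
#' @export
run_tracts <- function(cfg) {
  inp <- load_cfg_inputs(cfg, need_donor = TRUE)
  if (nrow(inp$spec$snps) == 0L) {
    stop("gtamp_no_snps: the donor carries no SNPs relative to the ",
         "reference, so conversion tracts cannot be traced; use a ",
         "SNP-bearing donor", call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- list()
  for (sid in names(inp$reads)) {
    reads <- inp$reads[[sid]]
    calls <- classify_reads(reads, inp$locus, inp$spec)
    gt_reads <- reads[calls$is_gt, , drop = FALSE]
    log_msg("[%s] %d GT-positive reads enter tract analysis", sid,
            nrow(gt_reads))
    if (nrow(gt_reads) == 0L) {
      message("[", sid, "] no GT reads; skipping tract summary")
      next
    }
    vectors <- lapply(seq_len(nrow(gt_reads)), function(i) {
      rd <- list(read_id = gt_reads$read_id[i],
                 ref_start = gt_reads$ref_start[i],
                 cigar = gt_reads$cigar[i], seq = gt_reads$seq[i])
      v <- mark_snp_states(rd, inp$spec, inp$locus)
      smooth_states(v, inp$spec, run_length = cfg$wt_run_length)
    })
    partial <- vapply(vectors, `[[`, logical(1), "partial_coverage")
    if (cfg$exclude_partial_coverage && any(partial)) {
      log_msg("[%s] %d partial-coverage reads excluded", sid, sum(partial))
      vectors <- vectors[!partial]
    }
    if (length(vectors) == 0L) next
    summaries[[sid]] <- summarize_tracts(vectors, inp$spec)
  }
  cfg_list <- unclass(cfg)
  snp_rows <- do.call(rbind, lapply(names(summaries), function(sid) {
    d <- summaries[[sid]]$per_snp
    cbind(data.frame(sample_id = sid, stringsAsFactors = FALSE), d,
          n_gt_reads = summaries[[sid]]$n_gt_reads)
  }))
  ext_rows <- do.call(rbind, lapply(names(summaries), function(sid) {
    cbind(data.frame(sample_id = sid, stringsAsFactors = FALSE),
          summaries[[sid]]$extents)
  }))
  hex_rows <- do.call(rbind, lapply(names(summaries), function(sid) {
    cbind(data.frame(sample_id = sid, stringsAsFactors = FALSE),
          summaries[[sid]]$hexbin)
  }))
  write_tsv_with_header(snp_rows %||% data.frame(),
                        file.path(cfg$out_dir, "tract_snp_freq.tsv"), cfg_list)
  write_tsv_with_header(ext_rows %||% data.frame(),
                        file.path(cfg$out_dir, "tract_extents.tsv"), cfg_list)
  write_tsv_with_header(hex_rows %||% data.frame(),
                        file.path(cfg$out_dir, "tract_hexbin.tsv"), cfg_list)
  if (isTRUE(cfg$plot) && length(summaries)) {
    plot_tracts(summaries, file.path(cfg$out_dir, "tract_plots.pdf"))
  }
  invisible(summaries)
}

# Tract diagram (per-SNP incorporation by distance) and a 2-D extent heatmap
# per sample, one page each.
plot_tracts <- function(summaries, path) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping plots")
    return(invisible(NULL))
  }
  grDevices::pdf(path, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  for (sid in names(summaries)) {
    s <- summaries[[sid]]
    p1 <- ggplot2::ggplot(s$per_snp,
                          ggplot2::aes(x = .data$distance,
                                       y = .data$pct_incorporated)) +
      ggplot2::geom_col(width = 3) +
      ggplot2::labs(title = sprintf("%s: donor SNP incorporation (n=%d GT reads)",
                                    sid, s$n_gt_reads),
                    x = "SNP position relative to insertion (bp)",
                    y = "GT reads with donor SNP (%)") +
      ggplot2::theme_minimal()
    print(p1)
    p2 <- ggplot2::ggplot(s$hexbin,
                          ggplot2::aes(x = .data$right_extent,
                                       y = .data$left_extent,
                                       fill = .data$count)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(title = sprintf("%s: conversion tract extents", sid),
                    x = "Right homology arm position (bp)",
                    y = "Left homology arm position (bp)") +
      ggplot2::theme_minimal()
    print(p2)
  }
  invisible(path)
}

#' Simulate a complete synthetic experiment
#'
#' Generates a synthetic locus and donor under the configured geometry and a
#' set of aligned reads with ground truth (see [sim_config()],
#' [make_locus_and_donor()], [simulate_reads()]).
#'
#' @param cfg A `sim_config`.
#' @param out_dir Output directory.
#' @return The file paths and truth table from [simulate_reads()], plus
#'   `locus` and `donor`.
#' @export
run_simulate <- function(cfg, out_dir) {
  sim <- make_locus_and_donor(cfg)
  out <- simulate_reads(cfg, sim, out_dir)
  log_msg("simulated %d reads (%d GT, %d background-indel) at %s",
          nrow(out$truth_table), sum(out$truth_table$is_gt),
          sum(out$truth_table$has_background_indel), out$sam)
  c(out, list(locus = sim$locus, donor = sim$donor))
}
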