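# shared SNP-donor fixture: 500 bp arms, SNPs every 50 bp, 18 bp insertion
tract_fixture <- function(seed = 15) {
  cfg <- sim_config(seed = seed, snp_spacing = 50L)
  sim <- make_locus_and_donor(cfg)
  list(cfg = cfg, sim = sim, spec = build_donor_spec(sim$donor, sim$locus))
}

test_that("mark_snp_states scores donor, reference, third-base and deleted positions", {
  fx <- tract_fixture()
  locus <- fx$sim$locus; spec <- fx$spec
  cut <- locus$cut_site
  L <- nchar(locus$sequence)
  full_cigar <- sprintf("%dM18I%dM", cut, L - cut)

  # read carrying the full donor arms: every SNP DONOR
  donor_read <- read_from_cigar(locus, 0L, full_cigar,
                                ins_seq = spec$insertion_sequence)
  ch <- strsplit(donor_read$seq, "")[[1]]
  q_of_ref <- function(p) p + 1L + ifelse(p >= cut, 18L, 0L)  # query index, 1-based
  ch[q_of_ref(spec$snps$ref_pos)] <- spec$snps$donor_base
  donor_read$seq <- paste(ch, collapse = "")
  v <- mark_snp_states(donor_read, spec, locus)
  expect_true(all(v$states == "DONOR"))
  expect_false(v$partial_coverage)

  # bare-insertion read: every SNP WT
  wt_read <- read_from_cigar(locus, 0L, full_cigar,
                             ins_seq = spec$insertion_sequence)
  expect_true(all(mark_snp_states(wt_read, spec, locus)$states == "WT"))

  # a third base (neither ref nor donor) is WT
  third <- wt_read
  ch <- strsplit(third$seq, "")[[1]]
  i <- q_of_ref(spec$snps$ref_pos[1])
  ch[i] <- setdiff(c("A", "C", "G", "T"),
                   c(spec$snps$ref_base[1], spec$snps$donor_base[1]))[1]
  third$seq <- paste(ch, collapse = "")
  expect_true(all(mark_snp_states(third, spec, locus)$states == "WT"))

  # a deletion spanning one SNP scores WT there, neighbors unaffected
  snp <- spec$snps[spec$snps$arm == "right", ][2, ]  # distance 100
  del_read <- donor_read
  a <- snp$ref_pos - 1L
  del_read$cigar <- sprintf("%dM18I%dM3D%dM", cut, a - cut, L - a - 3L)
  qdrop <- q_of_ref(a):(q_of_ref(a) + 2L)
  ch <- strsplit(del_read$seq, "")[[1]]
  del_read$seq <- paste(ch[-qdrop], collapse = "")
  v <- mark_snp_states(del_read, spec, locus)
  expect_equal(v$states[spec$snps$ref_pos == snp$ref_pos], "WT")
  expect_true(all(v$states[spec$snps$ref_pos != snp$ref_pos] == "DONOR"))

  # truncated read: uncovered SNPs are WT and flagged partial
  part <- read_from_cigar(locus, 0L, sprintf("%dM18I100M", cut),
                          ins_seq = spec$insertion_sequence)
  vp <- mark_snp_states(part, spec, locus)
  expect_true(vp$partial_coverage)
  expect_true(all(vp$states[spec$snps$ref_pos >= cut + 100L] == "WT"))
})

test_that("smoothing truncates beyond the first WT run and fills the interior", {
  spec5 <- spec_stub(rep("right", 5))
  # [DONOR, WT, WT, WT, DONOR] -> outer DONOR removed
  v <- smooth_states(snp_vec(c("DONOR", "WT", "WT", "WT", "DONOR")), spec5)
  expect_equal(v$states, c("DONOR", "WT", "WT", "WT", "WT"))

  spec7 <- spec_stub(rep("right", 7))
  # truncation then fill-in of the interior WT
  v2 <- smooth_states(
    snp_vec(c("DONOR", "WT", "DONOR", "WT", "WT", "WT", "DONOR")), spec7)
  expect_equal(v2$states,
               c("DONOR", "DONOR", "DONOR", "WT", "WT", "WT", "WT"))

  # all-WT unchanged; all-DONOR unchanged
  expect_equal(smooth_states(snp_vec(rep("WT", 7)), spec7)$states, rep("WT", 7))
  expect_equal(smooth_states(snp_vec(rep("DONOR", 7)), spec7)$states,
               rep("DONOR", 7))

  # the left arm is scanned outward (from the insertion toward the arm end):
  # catalog order for the left arm is outermost-first, so the same pattern
  # must be applied reversed
  specL <- spec_stub(rep("left", 5))
  vL <- smooth_states(snp_vec(c("DONOR", "WT", "WT", "WT", "DONOR")), specL)
  expect_equal(vL$states, c("WT", "WT", "WT", "WT", "DONOR"))

  expect_error(smooth_states(snp_vec(rep("WT", 5)), spec5, run_length = 0),
               "gtamp_bad_run_length")
})

test_that("smoothing is idempotent and yields prefix tracts bounded by the WT run", {
  spec2 <- spec_stub(c(rep("left", 8), rep("right", 8)))
  withr::with_seed(77, {
    for (i in 1:300) {
      states <- sample(c("DONOR", "WT"), 16, replace = TRUE,
                       prob = c(0.35, 0.65))
      v1 <- smooth_states(snp_vec(states), spec2)
      v2 <- smooth_states(v1, spec2)
      expect_identical(v1$states, v2$states)

      for (arm in c("left", "right")) {
        idx <- which(spec2$snps$arm == arm)
        ord <- order(abs(spec2$snps$distance[idx]))   # outward order
        sm <- (v1$states[idx] == "DONOR")[ord]
        orig <- (states[idx] == "DONOR")[ord]
        # prefix property: DONOR states form a contiguous prefix
        if (any(sm)) expect_true(all(sm[seq_len(max(which(sm)))]))
        # nothing DONOR at or beyond the first run of 3 consecutive WT
        run_end <- NA_integer_
        cnt <- 0L
        for (j in seq_along(orig)) {
          cnt <- if (orig[j]) 0L else cnt + 1L
          if (cnt == 3L) { run_end <- j; break }
        }
        if (!is.na(run_end)) {
          expect_false(any(sm[(run_end - 2L):length(sm)]))
        }
      }
    }
  })
})

test_that("tract extents report the outermost incorporated SNP per arm", {
  fx <- tract_fixture()
  spec <- fx$spec
  all_wt <- snp_vec(rep("WT", nrow(spec$snps)))
  expect_equal(tract_extent(all_wt, spec)[, c("left_extent", "right_extent")],
               data.frame(left_extent = 0L, right_extent = 0L))

  # left arm DONOR out to distance -150, right arm none
  states <- ifelse(spec$snps$arm == "left" & spec$snps$distance >= -150L,
                   "DONOR", "WT")
  ex <- tract_extent(snp_vec(states), spec)
  expect_equal(ex$left_extent, 150L)
  expect_equal(ex$right_extent, 0L)

  # full incorporation: outermost SNP on each arm (spacing 50 -> 500)
  full <- snp_vec(rep("DONOR", nrow(spec$snps)))
  exf <- tract_extent(full, spec)
  expect_equal(exf$left_extent, max(abs(spec$snps$distance)))
  expect_equal(exf$right_extent, max(abs(spec$snps$distance)))
})

test_that("summarize_tracts counts per-SNP frequencies and extent pairs", {
  fx <- tract_fixture()
  spec <- fx$spec
  n_snp <- nrow(spec$snps)
  full <- replicate(10, snp_vec(rep("DONOR", n_snp)), simplify = FALSE)
  s_full <- summarize_tracts(full, spec)
  expect_true(all(s_full$per_snp$pct_incorporated == 100))
  expect_equal(s_full$n_gt_reads, 10L)

  half <- c(replicate(5, snp_vec(rep("DONOR", n_snp)), simplify = FALSE),
            replicate(5, snp_vec(rep("WT", n_snp)), simplify = FALSE))
  s_half <- summarize_tracts(half, spec)
  expect_true(all(s_half$per_snp$pct_incorporated == 50))
  hx <- s_half$hexbin
  expect_setequal(hx$count, c(5L, 5L))
  expect_setequal(hx$left_extent, c(0L, 500L))
  expect_setequal(hx$right_extent, c(0L, 500L))

  expect_error(summarize_tracts(list(), spec), "gtamp_empty_input")
})

test_that("per-SNP frequency is non-increasing with distance after smoothing", {
  # error-free geometric tract simulation; smoothing is a no-op on clean
  # prefixes but is applied anyway, as in the pipeline
  cfg <- sim_config(seed = 16, n_reads = 1500L, gt_fraction = 1,
                    snp_spacing = 50L, tract_p = 0.5,
                    error_sub = 0, error_ins = 0, error_del = 0)
  sim <- make_locus_and_donor(cfg)
  out <- simulate_reads(cfg, sim, tempfile("geo"))
  reads <- load_alignments(out$sam, sim$locus)
  spec <- build_donor_spec(sim$donor, sim$locus)
  vectors <- lapply(seq_len(nrow(reads)), function(i) {
    smooth_states(mark_snp_states(reads[i, ], spec, sim$locus), spec)
  })
  s <- summarize_tracts(vectors, spec)
  for (arm in c("left", "right")) {
    d <- s$per_snp[s$per_snp$arm == arm, ]
    d <- d[order(abs(d$distance)), ]
    expect_true(all(diff(d$pct_incorporated) <= 1e-9))
  }
})

test_that("geometric tract simulation recovers the analytic survival function", {
  n <- 5000L
  p <- 0.5
  cfg <- sim_config(seed = 17, n_reads = n, gt_fraction = 1,
                    snp_spacing = 50L, tract_p = p,
                    error_sub = 0, error_ins = 0, error_del = 0)
  sim <- make_locus_and_donor(cfg)
  out <- simulate_reads(cfg, sim, tempfile("geo2"))
  reads <- load_alignments(out$sam, sim$locus)
  spec <- build_donor_spec(sim$donor, sim$locus)
  vectors <- lapply(seq_len(nrow(reads)), function(i) {
    smooth_states(mark_snp_states(reads[i, ], spec, sim$locus), spec)
  })
  s <- summarize_tracts(vectors, spec)
  # SNP j (outward index, 1-based) is incorporated iff K >= j where
  # K ~ min(Geom(p), 10): closed-form survival P = (1-p)^j for j < 10
  for (arm in c("left", "right")) {
    d <- s$per_snp[s$per_snp$arm == arm, ]
    d <- d[order(abs(d$distance)), ]
    for (j in seq_len(nrow(d))) {
      surv <- (1 - p)^j
      se <- sqrt(surv * (1 - surv) / n)
      expect_lt(abs(d$pct_incorporated[j] / 100 - surv), 3 * se + 1e-9)
    }
  }
  # empirical mean extent index matches the truncated-geometric mean
  k_emp <- rowSums(vapply(vectors, function(v) {
    vapply(c("left", "right"), function(a) {
      idx <- which(spec$snps$arm == a)
      sum(v$states[idx] == "DONOR")
    }, numeric(1))
  }, numeric(2))) / length(vectors)
  m <- 10L  # SNPs per arm
  mean_trunc <- sum((1 - p)^(1:m))  # E[min(Geom(p), m)] via survival sum
  se_mean <- sqrt(sum((1 - p)^(1:m) * (1 - (1 - p)^(1:m))) / n)  # upper bound
  expect_lt(abs(k_emp[["left"]] - mean_trunc), 4 * se_mean)
  expect_lt(abs(k_emp[["right"]] - mean_trunc), 4 * se_mean)
})
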