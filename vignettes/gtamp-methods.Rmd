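---
title: "Quantifying gene-targeting outcomes and conversion tracts from long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-targeting outcomes and conversion tracts from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtamp)
```

## The problem

Gene targeting (GT) modifies a locus by homologous recombination from a
supplied donor template. Quantifying GT molecularly is hard when donor
molecules are still present: primers inside the homology arms amplify the
donor as well as the locus, and primers outside the arms produce amplicons
too long for short-read sequencing. Long-read (nanopore) amplicon sequencing
removes the length restriction but brings a high per-base error rate
(roughly 10% for R9.4.1 single reads), so any analysis must distinguish true
editing outcomes from pervasive sequencing noise.

`gtamp` analyzes aligned long-read amplicons for three outcomes:

1. **Targeted mutagenesis** — indels from imprecise repair at the nuclease
   cut site, estimated with key-wise background subtraction against a
   no-nuclease control;
2. **Gene targeting** — reads carrying the donor's intended insertion,
   detected by fuzzy (Levenshtein) matching;
3. **Conversion tracts** — how far donor sequence was copied into the locus
   on each side of the insertion, phased per read via donor-specific SNPs.

A read simulator with per-read ground truth reproduces the study geometry
(500 bp homology arms, an 18 bp or 3 bp insertion at the predicted cut site,
engineered SNPs every 30 or 50 bp) so every stage is testable without
sequencing data.

## Inputs and coordinate conventions

The package consumes a reference amplicon FASTA with the predicted cut-site
coordinate, a donor FASTA, and aligned reads in SAM/BAM (one file per
sample, or a read-group `SM` tag). Alignment itself is out of scope: reads
are expected to come from a long-read aligner such as minimap2.

All internal coordinates are 0-based; SAM's 1-based `POS` is converted
exactly once, in `load_alignments()`. The *target window* is the closed
interval `cut_site ± window_halfwidth` (default ±4 bp). Secondary and
supplementary alignments are excluded so a chimeric amplicon molecule is
never counted twice; the default `min_mapq = 1` drops only mapq-0
multimappers, since no stricter published filter exists. Every filtering
step's count is retained for audit.

## Donor model

`build_donor_spec()` aligns the donor to the reference (global in the donor,
local in the reference; match +1, mismatch −1, gap open 4, gap extend 1) and
requires the donor to decompose as *left homology arm + one contiguous
insertion + right homology arm*. The insertion is left-aligned, as in
standard variant normalization, so its coordinate is deterministic when
flanking bases make placements equivalent. Arm mismatches become the ordered
donor-SNP catalog. SNP positions are reported as signed distances from the
insertion (negative = left arm), the convention used on conversion-tract
plots. Donors encoding deletions or several insertions are rejected rather
than guessed at.

## Targeted mutagenesis

`extract_window_variants()` walks each read's CIGAR with reference and query
cursors and keeps insertions anchored in the closed target window and
deletions whose span overlaps it. Variants are keyed by *(type, position,
length)*; the inserted sequence is deliberately not part of the key, because
per-base errors would fragment sequence-exact keys into singletons.
Substitutions never enter the mutagenesis statistic.

Because nanopore error produces indels at percent-level frequencies even in
untreated samples, raw variant frequencies overstate mutagenesis. The
estimator is therefore subtractive: for every key, the control sample's
frequency is subtracted from the treated sample's, and the *adjusted
targeted mutagenesis frequency* is the sum of the positive differences that
exceed 0.5%. The threshold is applied **after** subtraction — the
alternative (pre-subtraction thresholding) would silently drop genuine
low-frequency signal sitting on top of background, and the subtractive logic
only makes sense applied to the corrected quantity. With no control the
package degrades to thresholding raw frequencies and warns prominently.

The subtract-and-threshold estimator is not unbiased, and users should know
its two error terms. Because only *positive* post-subtraction differences
above 0.5% are summed, sampling noise on the many percent-level error keys
occasionally crosses the threshold and adds spurious signal in quanta of at
least 0.5%; and sequencing errors inside or adjacent to a true indel move a
fraction of its reads to neighboring (type, position, length) keys, which
are recaptured only when they exceed the threshold themselves. In the
package's simulation suite (10,000 reads per sample, default error rates)
the net effect is a bias of a few tenths of a percent — comparable to three
binomial standard errors at low or high spike-in fractions, which is why the
recovery tests at 2% and 30% sit outside a pure 3-SE band while 10% sits
inside. At these operating conditions the estimator is accurate to roughly
half a percentage point, not to sampling error.

GT-positive reads are excluded from the mutagenesis table by default: GT and
mutagenesis are separate outcomes, and counting the donor insertion as
"mutagenesis" would inflate both. A flag restores the inclusive behaviour.

## Gene-targeting detection

A read's candidate insertion is the concatenation, in read order, of all
insertions anchored in the target window; long insertions in high-error
reads are routinely split into several `I` operations, and merging them
recovers the full event while the distance cap below keeps false positives
controlled. The read is GT-positive when the Levenshtein distance between
candidate and expected insertion is at most

```
threshold = floor(length(expected insertion) / 3)
```

i.e. 6 edits for an 18 bp insertion and 1 edit for a 3 bp insertion.
Rounding is downward — conservative, and consistent with both published
anchor points. The Levenshtein distance is computed by bottom-up dynamic
programming in `levenshtein()`; the test suite checks it against a naive
recursive oracle, a memoised top-down recursion, and base R's `adist()`.

## Conversion tracts

For each GT-positive read, `mark_snp_states()` finds the read base aligned
to every cataloged SNP position: the donor base scores `DONOR`, anything
else (reference base, third base, deleted or uncovered position) scores
`WT`. States are strictly binary; treating noise as WT is conservative, and
interior miscalls are rescued by fill-in below. Reads that do not span the
full catalog are flagged `partial_coverage` and can be excluded.

`smooth_states()` applies two rules per arm, scanning outward from the
insertion:

1. **Truncation** — at the first run of 3 consecutive WT SNPs, every SNP
   beyond the run is set WT. The run itself stays WT (a literal reading of
   "external to"), and scanning outward rather than inward is what confines
   residual background to the innermost SNPs.
2. **Fill-in** — WT positions inside the putative tract (bounded by the
   outermost surviving DONOR state) are set DONOR, correcting donor SNPs
   erased by sequencing error. All interior positions are filled, not only
   isolated singletons: a tract is by definition contiguous donor sequence.

Truncation runs first, fill-in second; fill-in corrects removals *within the
tract determined by the previous step*. The result is idempotent and always
a contiguous tract anchored at the insertion, so per-SNP incorporation
frequencies are non-increasing with distance. The per-read summary is the
pair of *extents* — the |distance| of the outermost incorporated SNP on each
arm (0 for none) — tabulated into a two-dimensional count matrix for
heatmap display with marginal histograms.

With ~1% residual noise per SNP (a substitution error hitting the one donor
base among three alternatives), spurious post-smoothing tracts are expected
at the innermost SNPs only; a surviving call beyond the third innermost SNP
requires a specific coincidence of two nearby errors (probability on the
order of 10⁻⁴ per read per arm). The suite asserts < 0.1% spurious
incorporation per SNP outside the three innermost, matching the qualitative
"virtually all background removed" behaviour; an exact-zero assertion would
be structurally unattainable at realistic read counts.

## The simulator

`make_locus_and_donor()` draws a uniform-random reference of
`2 × arm_length + 2 × flank` bp (defaults 500 and 50) with the cut site at
the center, and a donor carrying a random insertion at the cut site plus
optional engineered SNPs every `snp_spacing` bp outward on both arms
(positions colliding with the indel window are skipped). The insertion's
terminal bases are chosen to differ from their flanking reference bases so
its placement is unambiguous.

`simulate_reads()` emits full-length reads in three classes: wild-type,
GT (insertion plus a per-arm tract of the `k` innermost SNPs, `k ~
min(Geom(tract_p), n_SNPs)` independently per arm, default `tract_p` 0.5 —
consistent with the observed dominance of short tracts), and
background-indel (targeted mutagenesis). Errors are applied per base,
i.i.d.: substitution 3%, insertion 3%, deletion 4% (≈90% single-read
accuracy, R9.4.1-like); each insertion event extends with continuation
probability 0.25 (mean run 4/3), since nanopore insertions are not strictly
single-base. CIGARs are computed from the true edit script, so the SAM is
exact by construction, and a truth table records class and true extents per
read. Homopolymer-context error, read fragmentation and chimeras are *not*
modeled; passing tests demonstrate the pipeline's arithmetic and its error
accommodation under calibrated i.i.d. noise, not performance on any
particular real flow cell.

Background-indel reads draw their indel from a small per-sample spectrum
(default: one characteristic variant per sample, type-weighted 60/40
deletion/insertion, length 1 + Geom(0.6) capped at 20 bp). This mirrors real
cut-site repair, which is dominated by one or a few recurrent outcomes. A
uniform random 1–20 bp indel per read (available with
`mutagenesis_spectrum = 0`) spreads the signal across ~360 distinct keys,
each below the 0.5% reporting threshold — no subtraction-based estimator
could see it, and no real repair spectrum looks like that.

## Problem sizes and numerical choices

The test suite and acceptance script use simulations of 10,000 reads for
recovery experiments (binomial SE at f = 10% is ~0.3%), 50,000 reads for the
false-positive bound, and 1,500–5,000 reads for tract-model checks; these
sizes give 3-standard-error tests adequate power while keeping a full run in
the minutes range. Stochastic checks use fixed seeds and 3–4σ tolerances.
Determinism is byte-level: identical configuration (including seed) yields
identical SAM, truth, and TSV outputs, and every output file is stamped with
the package version, a configuration fingerprint, and input checksums.

## Known limitations

- The error model is i.i.d. and context-free; real nanopore error is
  homopolymer- and motif-dependent, so real background levels vary by locus
  (published no-nuclease backgrounds differ more than two-fold between
  amplicons).
- Donors must encode a single contiguous insertion; deletion or
  substitution-only donors are rejected.
- Mutagenesis frequencies depend on a matched control; without one the
  output is a thresholded raw rate, which overestimates at error-prone loci.
- Tract extents are reported per arm without classifying repair sub-pathways
  (unidirectional vs bidirectional tracts); the extent table preserves the
  phased information needed for that downstream interpretation.
- No UMI support: read counts, not molecule counts, are the denominator.
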