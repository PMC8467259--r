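Package: gtamp
Title: Gene-Targeting Outcomes and Conversion Tracts from Long-Read
    Amplicon Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CRISPR gene-targeting (GT) outcomes from long-read
    (nanopore) amplicon alignments. Extracts insertion and deletion variants
    near the predicted nuclease cut site from CIGAR strings, computes
    background-subtracted targeted-mutagenesis frequencies against a
    no-nuclease control, classifies reads as GT-positive by fuzzy
    (Levenshtein) matching of observed window insertions against the donor's
    expected insertion, and phases donor-SNP incorporation along each read to
    reconstruct homologous-recombination conversion tracts with
    error-smoothing rules suited to high per-base error rates. Includes a
    deterministic amplicon read simulator that emits valid SAM with per-read
    ground truth so the whole pipeline can be exercised without sequencing
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
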