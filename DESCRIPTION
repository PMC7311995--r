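Package: comrank
Title: Compensatory Mutation Design and Ranking for RNA-RNA Interaction Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects and ranks single-base-pair compensatory mutations (CoMs)
    for in vitro verification of predicted RNA-RNA interactions (RRIs), such
    as bacterial sRNA-mRNA pairs. Candidate base pairs are collected from the
    minimum-free-energy (MFE) interaction predicted under a simplified
    nearest-neighbor duplex model with pluggable accessibility penalties
    (optionally extended by boundary-unique suboptimal interactions), filtered
    by base-pair type and helix context, and mutated in nucleotide-flip or
    all-alternatives mode. Each candidate is evaluated across the four
    wildtype/mutant sequence combinations and ranked through a hierarchical
    classifier chain (mfeCover, an energy-difference classifier with alpha
    and beta thresholds) followed by minDeltaE sorting. A benchmark harness
    reproduces rank statistics, energy profiling with Welch and paired
    t-tests, alpha/beta threshold sweeps and classifier/sorter comparisons on
    user-supplied or synthetic known-CoM tables, and a seeded synthetic
    fixture generator provides ground-truth interacting pairs. An adapter
    accepts interaction predictions precomputed by external RRI tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
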