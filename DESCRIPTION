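Package: anchorchain
Title: Minimizer Seeding and Forward-Transformed Anchor Chaining for Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A seed-and-chain engine for long noisy reads. Builds a minimizer
    hash index of a reference, collects exact-match anchors for each read, and
    chains collinear anchors by 1-D dynamic programming. Two interchangeable
    chaining engines are provided: the classic sequential predecessor-order DP
    (with the MAX_SKIP speed heuristic configurable or disabled) and a
    forward-transformed successor-order DP with probe-based dynamic successor
    range selection and a condensed workload vector, designed to produce
    bit-identical chain scores, predecessors and chain-maximum arrays. Includes
    backtracking, primary/secondary chain classification with mapping quality,
    PAF output, read-length binning, and deterministic synthetic-data
    generators (planted anchor chains, simulated noisy reads, ONT-like read
    length sampling) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
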