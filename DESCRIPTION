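Package: kothello
Title: Two-Level Othello Index for k-mer Occurrence Queries Across
    Sequencing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a compressed presence/absence index of k-mers across many
    RNA-seq experiments using a two-level minimal-perfect-hashing classifier
    (Othello). Occurrence maps are stored under a hybrid codec (value list,
    prefix-coded delta list, bitmap) and retrieved in constant time per
    k-mer. Sequence queries return per-experiment k-mer hit maps and hit
    ratios. Includes the analytic false-positive probability model for alien
    k-mer queries, a noise-aware gene-fusion occurrence caller driven by
    junction-spanning k-mers, and a synthetic cohort generator with exact
    ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    Biostrings,
    optparse,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
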