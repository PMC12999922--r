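Package: sigtempo
Title: Temporal Mutational-Signature Analysis for Multi-Sample Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies multi-sample somatic SNVs into early (shared by all
    tumor samples of a patient) and late (non-shared) sets, builds SBS96
    trinucleotide profiles, refits them against a reference signature catalog
    with tumor-site-prioritized signature selection (restricted NNLS with
    prune-and-refit sparsification and a cosine-similarity-driven rescue
    step), and scores each fit with a frequency-weighted Signature Score,
    its standard error, and pairwise z-tests across sites and timing
    classes. Includes a synthetic-cohort simulator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
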