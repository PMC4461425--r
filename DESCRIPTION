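Package: otubench
Title: Benchmarking OTU Clustering Workflows for Length-Variable Amplicons
Version: 0.1.0
Authors@R:
    person("Otubench", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare metabarcoding data-processing workflows on
    length-variable rRNA amplicons (such as the 18S V4 region). Implements
    stringent (expected-error) and relaxed (average-quality) read filtering,
    dereplication with singleton policies, greedy centroid (UCLUST-style) and
    hierarchical (mothur-style) de novo OTU clustering at a divergence
    threshold, three gap identity definitions (no gaps, one gap, each gap)
    with explicit terminal-gap handling, mock-community evaluation (precision
    and species detection against a reference database), and a seeded
    simulator of 454-style length-variable amplicon communities with ground
    truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: MAFFT (optional, for multiple-sequence-alignment based
    hierarchical clustering of large datasets)
Config/testthat/edition: 3
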