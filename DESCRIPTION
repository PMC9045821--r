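Package: modprofiler
Title: Single-Molecule RNA Modification Profiling from Nanopore Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling RNA modifications on single molecules from
    nanopore direct RNA sequencing signal. A variable-order hidden Markov
    model aligns per-read event sequences to a branchable reference in which
    annotated positions carry both canonical and modified kmer hypotheses,
    and posterior decoding yields a per-read modification probability at
    every annotated site. Includes supervised median/MAD emission training
    from labelled read sets, reads-by-sites profile matrices with
    classification metrics, frequency-change and correlation-change
    statistics (chi-square, Fisher z, Empirical Brown's method),
    Ward hierarchical clustering of profiles and raw event means,
    comparative Kolmogorov-Smirnov site detection, and a synthetic
    event-level read simulator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
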