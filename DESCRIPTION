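Package: smtaom
Title: Single-Molecule Telomere Profiling from Optical Map Label Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for single-molecule telomere analysis by optical genome
    mapping. Models per-chromosome-arm reference label maps, simulates
    two-colour labelled single DNA molecules (genome-wide motif labels plus a
    telomere-specific label) with configurable measurement noise, assigns
    molecule fragments to chromosome arms by dynamic-programming alignment of
    label spacings, classifies every chromosome end as an end telomere, a
    telomere-free end, or a fusion with or without an interstitial telomeric
    sequence, quantifies telomere length from segment extent and fluorescence
    intensity across a 0.1-100 kb dynamic range, and computes per-arm and
    cohort-level summary statistics with contingency-table and Welch tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
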