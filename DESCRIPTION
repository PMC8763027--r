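Package: rnamorpho
Title: Morphospace Analysis of RNA Secondary-Structure Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying phenotype bias in the RNA
    sequence-to-secondary-structure genotype-phenotype map. Folds RNA
    sequences to dot-bracket structures, coarse-grains them into the
    five-level hierarchy of abstract shapes, estimates shape frequencies
    and neutral set sizes by uniform random sampling of sequences
    (G-sampling), sizes the morphospace of possible shapes by exact
    enumeration and asymptotic counting, and compares natural (or
    synthetic) sequence databases against G-sampled spectra via
    rank-frequency curves, log-log correlation, coverage, and
    overrepresentation tests.
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
    withr
Config/testthat/edition: 3
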