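Package: neoforge
Title: Neoantigen Candidate Construction and Filtering from Annotated Somatic Variants
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs mutant protein sequences from annotated somatic
    variants (missense, in-frame indel, frameshift, gene fusion), extracts
    mutation-anchored MHC class I (8-11mer) and class II (15-30mer) peptide
    windows, assembles customized proteogenomic search databases, classifies
    peptide-HLA binders from percentile-rank affinity tables, and applies a
    four-stage candidate-neoantigen filter cascade (transcript expression,
    mass-spectrometry evidence, similarity to a curated neoantigen peptide
    database, and strict affinity/abundance thresholds) with matching-ratio
    reporting. Includes a deterministic mock binding predictor and a
    seeded synthetic-fixture generator so the whole pipeline runs and is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
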