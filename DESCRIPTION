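Package: splicephys
Title: Splicing-Isoform Composition and Electrophile Dose-Response Analysis
    for TRPA1 Channels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking the splicing-isoform composition of the
    insect TRPA1 channel to cellular electrophile sensitivity. Implements
    heat-normalized dose-response estimation from two-electrode voltage
    clamp recordings (three-parameter log-logistic fits yielding EC50 and
    maximum normalized current), best-hit classification of long amplicon
    reads against isoform references with length and identity filters,
    multinomial composition estimation with bootstrap intervals and
    small-integer ratio approximation, additive response modelling of
    isoform mixtures with simplex-constrained weight recovery, and scoring
    plus zero-dose normalization of proboscis extension reflex assays.
    Ships seeded synthetic-data generators for oocyte recordings,
    nanopore-like amplicon reads over toy isoform references, and
    behavioral trial tables with known ground truth, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
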