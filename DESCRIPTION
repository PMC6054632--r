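Package: brustab
Title: RNA Stability Analysis from Bromouridine Pulse-Chase Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide RNA stability analysis for bromouridine
    pulse-chase sequencing (Bru-seq / BruChase-seq) experiments.
    Computes per-transcript stability indices (chase/pulse RPKM ratios),
    classifies differential stability between conditions, tests
    differential synthesis on pulse counts with a negative-binomial Wald
    test, performs hypergeometric gene-set over-representation analysis,
    associates stability with transcript features and 3'UTR motifs, and
    relates RNA stability to protein abundance by regression and
    concordance analysis. Includes a kinetic synthetic-data generator
    (first-order decay, compositional library sampling, negative-binomial
    replicate noise, pathway-structured effects, coupled protein
    abundances) so the whole pipeline can be exercised end-to-end with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
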