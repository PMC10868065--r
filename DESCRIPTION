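Package: xprevo
Title: Cross-Species Expression Evolution Analysis for Polyploid Plant Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of leaf transcriptome evolution
    across diploid and allopolyploid species, with allopolyploid subgenomes
    treated as independent organisms. Implements trimming of orthogroups to
    one-to-one ortholog sets by homology filtering and total-bit-score
    maximization, expression-content and expression-level similarity analyses,
    expression distances and neighbor-joining expression trees under a
    stationary Ornstein-Uhlenbeck model with gene-resampling bootstrap,
    ancestral transcriptome inference by Brownian-motion pruning,
    classification of expression-level dominance in allopolyploids from the
    mid-parent dominance/additivity ratio, pathway-level relative-rate tests,
    and Bayesian estimation of gene-specific expression conservation with a
    gamma prior. Includes a synthetic-data generator that emulates the full
    analysis world with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
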