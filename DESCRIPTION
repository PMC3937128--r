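Package: ThreadMC
Title: Monte Carlo Protein Threading and Structure Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Block-encoded protein-protein alignment by stochastic search.
    Alignments between a query and a template protein are represented as
    ordered lists of gapless blocks and optimized by simulated annealing or
    replica-exchange Monte Carlo over seven block-modification movers,
    scored by a composable force field of sequence, profile,
    secondary-structure, solvent-accessibility, contact-potential and
    structure-based (TM-score, RMSD, DALI) energy terms. Supports threading
    of a sequence or profile onto a template structure, structure-structure
    alignment with a negative TM-score energy, scoring of arbitrary
    user-supplied alignments, and ranked suboptimal alignment generation
    with PIR (Modeller) output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d,
    optparse,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
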