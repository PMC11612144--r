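Package: qpisa
Title: Quantitative Protease Specificity Inference from Substrate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers exopeptidase cleavage specificity from quantified peptide
    mixtures exposed to an enzyme versus a buffer control. Peptides are mapped
    to a protein database and classified as tryptic substrates or semi-tryptic
    products; per-peptide cleavage-oriented log2 fold changes are modelled as a
    linear function of N-terminal residue identities (dummy-coded) with
    pairwise subsite interaction terms; fitted coefficients are rearranged
    into cooperative cleavage-motif tables (P1, P2:P1, P1:P1') that score
    arbitrary peptides and render as sequence logos. A seeded synthetic
    experiment generator (skewed proteome, in-silico tryptic digestion,
    motif-driven dipeptidyl cleavage with first-order kinetics, replicate
    noise and left-censored dropout) makes the whole pipeline testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
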