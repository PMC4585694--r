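Package: frustrace
Title: Combined Evolutionary Conservation and Local Frustration Analysis of
    Protein Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-residue analysis of protein structures and sequence families
    that combines local energetic frustration with evolutionary conservation.
    Local frustration is quantified by a single-residue mutational-decoy
    Z-score (SRLF index) computed from a configurable 20x20 residue-pair
    contact potential; conservation by a real-value Evolutionary-Trace-style
    rank built from Shannon entropies of alignment sub-groups defined by
    successive partitions of a phylogenetic tree. Residues are classified
    into a six-class scheme crossing minimally frustrated, neutral and highly
    frustrated states with conserved and non-conserved states, aggregated
    across ensembles of complexes, compared between target-bound and unbound
    states, and rescored under fixed-backbone point variants. A synthetic
    data module generates ground-truth-labelled structures, complexes and
    simulated alignments so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ape,
    phangorn,
    seqinr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
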