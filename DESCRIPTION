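Package: foldcontacts
Title: Residue Contact Definitions for Protein Fold Recognition
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds residue-residue contact maps of protein structures under
    parameterized contact definitions (contact base, distance cutoff, minimum
    sequence separation), scores pairs of structures by the fraction of common
    contacts (FCC) through a residue-level alignment, and evaluates how well
    each contact definition separates same-fold from different-fold pairs
    using fold-averaged ROC curves and AUC. Includes readers for PDB
    coordinates, aligned FASTA and TM-align alignment output, a synthetic
    generator of fold families (ideal helices and beta sheets with coordinate
    noise and threading-like alignment corruption), and a small command-line
    workbench orchestrating the full experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
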