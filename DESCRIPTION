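Package: thymorep
Title: Simulation and Analysis of Foetal and Adult Thymocyte TCR Repertoires
Version: 1.0.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for clonotype-level analysis of mouse thymocyte T-cell
    receptor (TCR) alpha- and beta-chain repertoires across life stages,
    together with a V(D)J rearrangement simulator that emulates
    life-stage-dependent repertoire structure (short foetal non-template
    insertions, chromosomally proximal V-J pairing, progressive TRA
    rearrangement, clonal expansion, and lineage-specific selection).
    Implements discrete power-law maximum-likelihood fitting of clone-size
    spectra, rarefied Shannon, Gini and Jaccard diversity indices,
    combinatorial VxJ differential-usage tiling with Benjamini-Hochberg FDR
    control, CDR3 junction decomposition and non-template insertion
    inference, CDR1xCDR2 recoding of V usage, and the log10/z-score/PCA
    multivariate procedure, plus an end-to-end cohort pipeline and a small
    command-line interface. Reads and writes AIRR Rearrangement TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
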