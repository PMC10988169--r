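Package: qtykit
Title: QTY-Code Analysis of Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and characterising water-soluble variants of
    alpha-helical membrane proteins with the QTY substitution code (L to Q,
    I and V to T, F to Y, applied inside annotated transmembrane spans).
    Provides sequence-level characterisation (variation percentages,
    isoelectric point by the Bjellqvist pKa model, average molecular weight,
    Kyte-Doolittle hydropathy), structure superposition by the Kabsch
    algorithm with iterative outlier rejection, transmembrane-domain-only
    comparisons, Shrake-Rupley solvent-accessible surface area with a
    hydrophobic-surface-fraction statistic, and a synthetic multi-pass
    membrane-protein generator (sequences, topologies and consistent
    alpha-helical bundle coordinates) for end-to-end testing without
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
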