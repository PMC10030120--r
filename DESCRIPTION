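Package: fpnbind
Title: Quantitative Binding and Transport Assay Analysis for Ferroportin Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the biophysical characterization of the
    iron exporter ferroportin and small-molecule or peptide inhibitors such
    as vamifeport and hepcidin. Implements fluorescence-polarization (FP)
    direct-binding and displacement assays with a two-stage dissociation
    constant (KD) inference chain (global saturation fits with shared
    parameters, four-parameter Hill IC50 fits, and competition-model KD
    fits in fractional-saturation space), thermal-stability melting-curve
    (Tm) analysis, proteoliposome transport initial-rate and Michaelis-Menten
    KM estimation, and global 1:1 Langmuir kinetic fits of surface plasmon
    resonance sensorgrams. Includes seeded synthetic-data generators that
    emulate each assay design so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
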