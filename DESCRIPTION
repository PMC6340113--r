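Package: camtitr
Title: Two-Dimensional Fluorescence-Anisotropy Titration Analysis of
    Calmodulin-Peptide Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for two-dimensional fluorescence-anisotropy
    (FA) titrations of calmodulin (CaM) against fluorophore-labelled
    CaM-binding-domain (CaMBD) peptides on 384-well plates (16 free-Ca2+
    rows by 24 serial-dilution columns). Provides EGTA/NTA free-calcium
    buffer speciation and mixing-series design, exact 1:1 ligand-depletion
    and two-mode binding isotherms, row-wise nonlinear least-squares
    estimation of dissociation constants with asymptotic confidence
    intervals and model selection, column-wise Hill fits for apparent
    Ca2+ affinities of CaM/peptide complexes, fold-change and
    CI-overlap reporting, and a seeded synthetic-plate generator that
    emulates the assay for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
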