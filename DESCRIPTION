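Package: il2cohort
Title: Cohort-Level Modeling of Antigen-Driven IL-2 Production, Consumption
    and Signaling Cross-Talk in T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic cohort model of the interleukin-2 (IL-2) pathway in
    antigen-activated T cells: a stiff ordinary-differential-equation system
    coupling per-cell TCR engagement, IL-2 receptor expression, STAT5
    phosphorylation and an autocatalytic acceleration ("Boost") of per-cell
    IL-2 secretion to shared extracellular antigen and IL-2 pools. Includes
    model variants (classical pathway, no TCR-pSTAT5 cross-talk, no secretion
    boost, JAK blockade), condition sweeps with power-law fitting of peak IL-2
    against T-cell number and antigen dose, two-clone mixed-culture
    simulations, cell-to-cell variability analysis (receptor-binned Hill fits
    of pSTAT5 dose responses), SlopeXtalk antigenicity calibration, and
    synthetic flow-like and ELISA-like data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
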