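Package: ifflcyto
Title: Steady-State Models, Dynamics and Cytometry Analysis for
    EndoRNase-Based Incoherent Feedforward Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and analysis tools for endoRNase-based incoherent
    feedforward loop (iFFL) gene-expression controllers under
    transcriptional resource competition. Provides closed-form
    steady-state models of iFFL output versus plasmid dose, free
    resources and transfection-marker level; a mass-action ODE
    simulator of iFFL dynamics during transient transfection with
    plasmid dilution; a synthetic-data generator emulating
    transient-transfection flow cytometry; the event-processing
    pipeline (MEFL bead calibration, autofluorescence subtraction and
    linear compensation, threshold gating, binning, median summaries,
    scatter density, cell-density estimation); robustness and
    adaptation metrics; and least-squares fitting of the iFFL,
    unregulated-control and resource-competition dose-response models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    fitdistrplus,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
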