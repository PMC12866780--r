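Package: mechisto
Title: Multiscale Tissue Biomechanics, Quantitative Histology, and
    Single-Cell Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for multiscale characterization
    of soft tissue. Fits Sneddon's flat-punch solution to stepped local
    indentation data, neo-Hookean and nonlinear Maxwell-Wiechert
    (two-element) viscoelastic models to unconfined compression
    stress-relaxation data, quantifies collagen content and birefringence
    classes from Masson's trichrome and Picrosirius-red stains by HSL
    colorimetry, summarizes collagen fiber architecture with circular
    statistics (Orientation Index), assigns single-cell phenotypes from
    morphology and marker intensities via graph clustering, and provides
    the Scheirer-Ray-Hare two-factor rank test with Dunn-Bonferroni
    post-hoc comparisons. Includes synthetic-data generators with known
    ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    minpack.lm,
    png,
    tiff,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
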