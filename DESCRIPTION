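Package: osteosig
Title: NMR Metabolomic Marker Discovery for MSC Osteodifferentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering donor-independent metabolite signatures of
    mesenchymal stem cell osteodifferentiation from 1H NMR spectra of cell
    extracts and conditioned media. Provides a ground-truth-annotated
    synthetic cohort simulator (Lorentzian multiplet spectra or integral
    tables), spectral preprocessing (TSP referencing, region exclusion,
    recursive segment-wise alignment, total-area normalization), a recursive
    blank-referenced correction of conditioned-media values across repeated
    media exchanges, window integration and marker ratios, PCA and NIPALS
    PLS-DA with VIP scores and back-transformed loadings, Monte Carlo
    cross-validation (Q2, sensitivity, specificity, classification rate),
    exact Wilcoxon rank-sum screening with percent-variation trajectories,
    donor-independent signature selection, and thresholded Spearman
    correlation maps, orchestrated by a reproducible pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    ggplot2,
    withr
Config/testthat/edition: 3
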