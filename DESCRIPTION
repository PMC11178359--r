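Package: socialgrid
Title: Grid-Like Code and Distance Code Analysis for Navigation of
    Abstract 2D Cognitive Maps
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quadrature-filter general linear models, leave-one-run-out
    grid-orientation consistency analysis with control periodicities,
    distance-coding GLMs, least-squares-separate representational
    similarity analyses, circular statistics on grid orientations,
    behavioral map-formation indices and temporal signal-to-noise quality
    control for fMRI studies of hexadirectional (grid-cell-like)
    modulation during navigation of abstract two-dimensional spaces, such
    as a social value map spanned by competence and trustworthiness.
    Includes a synthetic-data generator that emulates the trajectory
    recall task and the BOLD signal model, so the whole pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
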