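Package: tilreact
Title: Detection of Tumor-Specific Reactive TILs by Flow Gating, Paired
    Expression and Single-Cell Marker Positivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying tumor-specific reactive tumor-infiltrating
    lymphocytes (TILs). Implements threshold gating of flow-cytometry event
    tables with Boolean-combination profiling of CD137, TNF, IFN-gamma and
    CD107a, background subtraction against unstimulated controls with the
    0.01/100 percent clamping convention, and inhibitor-modulation analysis of
    surface versus intracellular CD137. Derives tumor-specific activation gene
    sets from paired autologous/allogeneic bulk expression via per-patient
    log2 fold changes and paired t-tests, with top-K rank validation against
    antigen-specific references. Classifies single cells in situ by binary
    marker-gene positivity (TNFRSF9, TNF, IFNG; ENTPD1/ITGAE) into functional
    clusters and summarizes gene sets and signature panels as cross-cluster
    Z-score heatmaps. Ships synthetic-data generators with known ground truth
    for flow events, paired bulk expression and sparse single-cell counts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
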