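Package: ckdms
Title: Molecular Scoring of Tubulointerstitial Damage in Chronic Kidney Disease Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for one-color microarray profiles of renal
    biopsies in chronic kidney disease. Starting from probe-level fluorescence
    intensities with feature background statistics and bad-spot flags, the
    package performs median normalization, background-significance
    detectability filtering, and fold-change computation against a normal
    kidney control profile; selects up- and down-regulated genes by a z-score
    rule on log2 cohort-mean ratios; tests candidate genes against ordinal
    histopathology grades of tubulointerstitial fibrosis and tubular cell
    damage with the Kruskal-Wallis test; and summarises a five-gene marker
    panel (HAVCR1/KIM-1, LCN2/NGAL, SOX9, WFDC2, NKX6-2) as the geometric mean
    of unlogged fold changes, with ROC/Youden-derived score thresholds that
    predict grade categories in new samples. A seeded synthetic-cohort
    generator with planted grade-driven markers makes every stage testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
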