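Package: akstrat
Title: Transcriptomic Stratification of Actinic Keratoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a squamous-cell-carcinoma-versus-healthy expression
    signature from paired reference skin samples via two competing
    differential-expression pipelines (a paired linear model with quantile
    normalization and Benjamini-Hochberg correction, and a two-group pooled
    t-test with 75th-percentile-shift normalization and Bonferroni
    correction), selects the better pipeline by nearest-centroid
    classification accuracy on a held-out test group, and stratifies actinic
    keratosis (AK) samples into healthy-like (AK_NL) and carcinoma-like
    (AK_L) subclasses by Euclidean distance to the reference-group centroids
    in signature PCA space. Includes downstream characterization
    (hierarchical clustering under uncentered correlation, AK-progression
    differential analysis, marker trend ANOVA with Tukey post-hoc tests)
    and a synthetic-cohort generator with planted fold changes so the whole
    pipeline is testable without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
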