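Package: pmtox
Title: Integrated Chemometric and Toxicological Evaluation of Herbal Batches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An integrated evaluation pipeline for the safety of commercial
    herbal batches, developed around Polygonum multiflorum (PM) decoction
    pieces. Combines chemical-profile chemometrics (autoscaling, PCA with
    cross-validated Q2, hierarchical clustering, two-class OPLS-DA with VIP
    and a 200x permutation test), univariate marker statistics (Welch t-tests,
    one-way ANOVA with Tukey HSD, Benjamini-Hochberg FDR), CCK-8 viability and
    four-parameter-logistic IC50 fitting with three-tier toxicity
    classification, a Loewe equivalent-dose "One-belt, One-line"
    combination-index analysis with synergy judgment, and chromaticity
    descriptors (E*ab, normalized RGB) linked to toxicity by regression.
    Includes a seeded synthetic-data generator emulating the 61-batch by
    26-compound study design so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
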