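Package: metabocv
Title: Cross-Validated OPLS-DA Profiling of 1H-NMR Plasma Metabolomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for 1H-NMR plasma metabolomics of factorial
    (genotype x diet) rodent cohorts. Provides spectral preprocessing (chemical-shift
    referencing to the lactate doublet, fixed-width binning, total-sum normalization,
    Pareto scaling), from-scratch PCA and two-class OPLS-DA with VIP scores, a
    repeated external cross-validation significance framework (stratified folds,
    internal cross-validation for orthogonal-component selection, permutation null,
    one-sided Kolmogorov-Smirnov test), VIP-driven metabolite region profiling, the
    univariate statistics layer (Shapiro-Wilk, two-way ANOVA with Tukey HSD, t tests),
    and small assay computations (OGTT AUC, comparative-Ct expression folds). A
    synthetic-cohort simulator with known ground truth makes every stage testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
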