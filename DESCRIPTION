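Package: oadfa
Title: Discriminant Function Analysis Pipelines for Osteoarthritis Biomarker Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-group canonical discriminant function analysis (DFA) of
    inflammatory blood biomarkers (IL-6, TNF-alpha, MPO) measured in plasma
    and serum from osteoarthritis patients and healthy volunteers, rebuilt
    as a tested pipeline. Covers SPSS-style preprocessing (linear
    interpolation of missing values, log10 transformation, pooled z-scoring),
    per-group normality assessment (Shapiro-Wilk, Lilliefors-corrected
    Kolmogorov-Smirnov, Q-Q coordinates), homogeneity and separation tests
    (Box's M with its F approximation, per-variable Wilks' lambda group-mean
    tests, overall Wilks' lambda with Bartlett's chi-square), Fisher
    classification with leave-one-out cross-validation and confusion
    summaries, Tukey-fence outlier detection on discriminant scores, and the
    iterative outlier-classification feedback loop that removes the most
    pronounced participant until model assumptions hold. A synthetic cohort
    generator with planted contamination and sporadic missingness stands in
    for the unavailable clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    zoo,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
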