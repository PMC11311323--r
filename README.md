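# oadfa — Discriminant Function Analysis Pipelines for Osteoarthritis Biomarker Cohorts

`oadfa` rebuilds, as a tested R package plus a small analysis workflow, a
biomarker-based discriminant classification study: can blood
concentrations of interleukin-6 (IL-6), tumour necrosis factor alpha
(TNF-α) and myeloperoxidase (MPO), measured in paired plasma and serum
specimens, separate osteoarthritis patients from healthy volunteers?

It is aimed at biostatisticians and methods-minded clinical researchers
who want the full pipeline — not just the final classifier — reproducible
and testable:

* **Preprocessing** the way legacy statistical software does it: linear
  interpolation of missing values (LINT), per-variable log10
  transformation, pooled z-scoring.
* **Assumption testing**: per-group Shapiro–Wilk and Lilliefors-corrected
  Kolmogorov–Smirnov normality tables, Q–Q plot coordinates, Box's M test
  of covariance homogeneity with its F approximation, per-variable Wilks'
  Λ group-mean tests, and the overall Wilks' Λ with Bartlett's χ².
* **Two-group canonical DFA**: for groups coded patient = 1 /
  volunteer = 2, the canonical function is the leading eigenvector of
  W⁻¹B — equivalently b ∝ S⁻¹(x̄₁ − x̄₂) — scaled to unit pooled
  within-group score variance, with standardized coefficients
  bᵢ·√Sᵢᵢ ranking the biomarkers, Fisher linear classification functions,
  leave-one-out cross-validation and SPSS-style confusion summaries.
* **The iterative feedback loop**: fit, flag Tukey-fence (boxplot)
  outliers on the discriminant scores, remove the most pronounced
  participant (both specimens together), re-test assumptions, repeat
  until they hold.
* **A synthetic cohort generator** (29 patients + 15 volunteers, paired
  specimens, log-normal marginals, within-participant correlation,
  sporadic missingness, planted contaminated participants) standing in
  for the clinical data, which is available only on request from its
  authors.

## Worked example

```r
library(oadfa)

# a study-like cohort: 58 patient + 27 volunteer cases, 4 contaminated
# participants, ~3% missing cells
cfg <- generator_config(seed = 3, contamination_rate = 0.1,
                        missing_rate = 0.03, drop_volunteer_cases = 3)
cohort <- generate_cohort(cfg)

# preprocess (LINT -> log10(MPO) -> z-scores) and fit
m <- build_matrix(cohort, transform_config())
fit <- fit_discriminant(m)
report <- confusion_summary(m$group, classify_cases(fit, m), loocv_classify(m))
round(standardized_coefficients(fit), 3)
#>    il6   tnfa    mpo
#> -0.868 -0.624  1.555
report$original$overall_percent_correct        # 67.1
report$cross_validated$overall_percent_correct # 64.7

# the feedback loop, on the fully logged matrix
res <- run_feedback_loop(cohort,
         transform_config(log10_variables = c("il6", "tnfa", "mpo")),
         loop_config(stop_requires = c("no_mild_outliers", "box_m_pass")))
res
#> Iterative DFA classification loop: 5 iteration(s), 4 participant(s) removed
#>   removal order: P12, V10, P05, V07
#>   terminated by: assumptions_met
#>   Box's M p: 0.6886 (pre) -> 0.4106 (post)
#>   overall % correct (cross-validated): 62.4 (pre) -> 71.4 (post)
true_parameters(cfg)$contaminated
#> [1] "P05" "P12" "V07" "V10"
```

The standardized coefficients rank MPO as the dominant discriminator, and
the loop removes exactly the four planted contaminated participants —
`P12, V10, P05, V07`, in outlier-severity order — before stopping with
covariance homogeneity restored. (Recovery is *not* guaranteed: clustered
mean-shift outliers partially mask themselves in a non-robust
discriminant fit; the methods vignette quantifies this.)

The same pipeline, narrated step by step with its output tables written
under `results/`, is in the numbered scripts:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_assumption_tests.R
Rscript analysis/04_discriminant_classification.R
Rscript analysis/05_feedback_loop.R
```

## Documentation

The methods vignette (`vignettes/oa-biomarker-dfa.Rmd`) documents the
model, the generator's design and defaults, every numerical convention
(quartile method, tie-breaks, the 0.200 Lilliefors cap, singularity
tolerances), the loop's stopping rules, and the package's known
limitations — in particular the outlier-masking ceiling of the feedback
loop on clustered contamination.
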