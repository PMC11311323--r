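# Build a cohort_matrix directly from a numeric matrix, bypassing the
# preprocessing pipeline, for tests that exercise the statistics alone.
mk_matrix <- function(X, grp, ids = NULL) {
  colnames(X) <- c("il6", "tnfa", "mpo")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  structure(list(case_index = as.character(seq_len(nrow(X))),
                 participant_id = ids,
                 group = as.integer(grp),
                 X = X,
                 variable_names = colnames(X),
                 transform = transform_config()),
            class = "cohort_matrix")
}

# Two multivariate-normal groups with a mean shift, as a cohort_matrix.
random_groups <- function(n1, n2, shift = 0.8, p = 3) {
  X <- rbind(matrix(rnorm(n1 * p), ncol = p),
             matrix(rnorm(n2 * p, mean = shift), ncol = p))
  mk_matrix(X, rep(1:2, c(n1, n2)))
}

# Transform configuration in which all three biomarkers are logged, so a
# generator cohort is exactly multivariate normal after preprocessing.
tc_log_all <- function() transform_config(log10_variables = c("il6", "tnfa", "mpo"))

# The contaminated study-emulation configuration used by the loop tests:
# 29 + 15 participants, 4 planted contaminated participants
# (floor(0.1 * 44)), sporadic missingness, 58/27 analysed cases.
study_config <- function(seed) {
  generator_config(seed = seed, contamination_rate = 0.1,
                   missing_rate = 0.03, drop_volunteer_cases = 3)
}
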