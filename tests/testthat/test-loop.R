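test_that("removal selection prefers extremes, then distance, then lower number", {
  rec <- function(pid, sev, d) data.frame(case_index = paste0(pid, ":p"),
                                          participant_id = pid, group = 1L,
                                          score = 0, severity = sev,
                                          distance_beyond_fence = d,
                                          stringsAsFactors = FALSE)
  # an extreme beats a mild with larger distance
  out <- rbind(rec("P07", "extreme", 2.0), rec("P02", "mild", 5.0))
  expect_equal(select_removal(out)$participant_id, "P07")
  # ties in severity and distance break toward the lower participant number
  out2 <- rbind(rec("P09", "mild", 1.0), rec("P04", "mild", 1.0))
  expect_equal(select_removal(out2)$participant_id, "P04")
  expect_error(select_removal(out2[0, ]), "empty outlier list")

  # brute-force max-scan oracle over random outlier lists
  set.seed(401)
  for (r in 1:20) {
    n <- sample(2:8, 1)
    ol <- do.call(rbind, lapply(seq_len(n), function(i) {
      rec(sprintf("P%02d", sample(1:30, 1)),
          sample(c("mild", "extreme"), 1), round(runif(1, 0.1, 3), 3))
    }))
    sel <- select_removal(ol)
    pool <- if (any(ol$severity == "extreme")) ol[ol$severity == "extreme", ] else ol
    best <- pool[pool$distance_beyond_fence == max(pool$distance_beyond_fence), ]
    expect_true(sel$participant_id %in% best$participant_id)
    expect_equal(sel$participant_id, sort(best$participant_id)[1])
  }
})

test_that("a clean multivariate-normal cohort stops at iteration 0", {
  co <- generate_cohort(generator_config(seed = 3))
  res <- run_feedback_loop(co, tc_log_all(), loop_config())
  expect_equal(res$terminated_by, "assumptions_met")
  expect_length(res$classified_participants, 0L)
  expect_length(res$iterations, 1L)
  expect_equal(res$iterations[[1]]$iteration, 0L)
  expect_true(is.na(res$iterations[[1]]$removed_participant))
})

test_that("planted contaminated participants are recovered in removal order", {
  cfg <- study_config(seed = 3)
  planted <- true_parameters(cfg)$contaminated
  res <- run_feedback_loop(generate_cohort(cfg), tc_log_all(), loop_config())
  k <- length(planted)
  expect_gte(length(res$classified_participants), k)
  expect_setequal(res$classified_participants[seq_len(k)], planted)
  expect_equal(res$terminated_by, "assumptions_met")

  # removal order equals the per-iteration log
  logged <- vapply(res$iterations, function(r) r$removed_participant, character(1))
  expect_equal(res$classified_participants, logged[!is.na(logged)])

  # a participant's specimen pair leaves together: case counts drop by 2
  drops <- diff(vapply(res$iterations, function(r) r$n_cases_before, numeric(1)))
  expect_true(all(drops < 0))
  expect_true(all(abs(drops) <= 2))

  # stopping conditions are true of the final retained set
  expect_gte(res$post_report$assumptions$box_m$p, 0.05)
  expect_true(all(res$post_report$normality$sw_p >= 0.05))
  expect_equal(nrow(res$post_report$outliers), 0L)

  # monotone bookkeeping: retained + removed = initial at the end
  n0 <- res$iterations[[1]]$n_cases_before
  removed_cases <- n0 - nrow(res$final_matrix$X)
  expect_equal(removed_cases,
               sum(abs(drops)))
})

test_that("the loop is deterministic given cohort and configuration", {
  cfg <- study_config(seed = 7)
  co <- generate_cohort(cfg)
  r1 <- run_feedback_loop(co, tc_log_all(), loop_config())
  r2 <- run_feedback_loop(co, tc_log_all(), loop_config())
  expect_identical(r1$classified_participants, r2$classified_participants)
  expect_identical(r1$terminated_by, r2$terminated_by)
  expect_equal(r1$post_report$assumptions$box_m$p,
               r2$post_report$assumptions$box_m$p)
})

test_that("the minimum-group-size guard stops the loop without an exception", {
  # tiny cohort with one planted extreme participant per group side:
  # any removal would leave the patient group below the floor
  cfg <- generator_config(n_patients = 3, n_volunteers = 4,
                          contamination_rate = 0.15,  # floor(1.05) = 1 planted
                          seed = 6)
  co <- generate_cohort(cfg)
  res <- run_feedback_loop(co, tc_log_all(),
                           loop_config(min_group_cases = 6L,
                                       stop_requires = "no_mild_outliers"))
  expect_true(res$terminated_by %in% c("min_group_size", "assumptions_met",
                                       "no_removable_outliers"))
  if (res$terminated_by == "min_group_size") {
    expect_true(all(table(res$final_matrix$group) >= 6L))
  }
})

test_that("report writing is complete and byte-stable", {
  cfg <- study_config(seed = 3)
  res <- run_feedback_loop(generate_cohort(cfg), tc_log_all(), loop_config())
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_reports(res, d1)
  write_reports(res, d2)
  expected <- c("pre_normality.tsv", "pre_box_m.tsv", "pre_group_mean_tests.tsv",
                "pre_wilks.tsv", "pre_coefficients.tsv", "pre_classification.tsv",
                "post_normality.tsv", "post_box_m.tsv", "post_group_mean_tests.tsv",
                "post_wilks.tsv", "post_coefficients.tsv", "post_classification.tsv",
                "iteration_log.csv", "run_summary.json")
  expect_true(all(file.exists(file.path(d1, expected))))
  for (f in expected) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  log <- read.csv(file.path(d1, "iteration_log.csv"))
  expect_equal(nrow(log), length(res$iterations))

  # a zero-removal run writes a single-record iteration log
  res0 <- run_feedback_loop(generate_cohort(generator_config(seed = 3)),
                            tc_log_all(), loop_config())
  d0 <- file.path(tempdir(), "rep0")
  write_reports(res0, d0)
  expect_equal(nrow(read.csv(file.path(d0, "iteration_log.csv"))), 1L)
})
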