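#' Configuration for the iterative outlier-classification loop
#'
#' @param alpha Significance level for the assumption checks (default 0.05).
#' @param removal_unit `"participant"` (default; all of a flagged
#'   participant's specimen cases are removed together, as plasma/serum
#'   pairs) or `"case"`.
#' @param max_iterations Maximum removal iterations; default (`NULL`) is the
#'   number of cases, which the strictly decreasing case count can never
#'   exceed.
#' @param min_group_cases Guard: the loop stops (recording
#'   `terminated_by = "min_group_size"`) rather than let a removal push any
#'   group below this many cases. Must be at least p + 1; default p + 2 = 5
#'   so every leave-one-out fit stays valid.
#' @param stop_requires Character subset of `no_extreme_outliers`,
#'   `no_mild_outliers` (no case beyond the inner fences, which implies no
#'   extremes), `box_m_pass` (Box's M p >= alpha), `shapiro_pass` (every
#'   per-group Shapiro-Wilk p >= alpha). The loop stops as classified when
#'   all hold. Default: `no_mild_outliers`, `box_m_pass`, `shapiro_pass`.
#' @param priors Prior mode passed to [fit_discriminant()].
#' @param quartile_method Passed to [tukey_outliers()].
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(alpha = 0.05,
                        removal_unit = c("participant", "case"),
                        max_iterations = NULL,
                        min_group_cases = 5L,
                        stop_requires = c("no_mild_outliers", "box_m_pass",
                                          "shapiro_pass"),
                        priors = c("equal", "proportional"),
                        quartile_method = c("hinges", "quantile")) {
  removal_unit <- match.arg(removal_unit)
  priors <- match.arg(priors)
  quartile_method <- match.arg(quartile_method)
  allowed <- c("no_extreme_outliers", "no_mild_outliers", "box_m_pass",
               "shapiro_pass")
  bad <- setdiff(stop_requires, allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown stop_requires condition(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (min_group_cases < 4L) {
    stop("min_group_cases must be at least p + 1 = 4", call. = FALSE)
  }
  structure(list(alpha = alpha, removal_unit = removal_unit,
                 max_iterations = max_iterations,
                 min_group_cases = as.integer(min_group_cases),
                 stop_requires = stop_requires, priors = priors,
                 quartile_method = quartile_method),
            class = "loop_config")
}

#' Select the next removal from an outlier list
#'
#' Extreme outliers take precedence over mild ones; among equals the record
#' with the largest `distance_beyond_fence` wins, with ties broken toward
#' the lower participant number. With `unit = "participant"` the winning
#' record's participant is returned and all of that participant's cases are
#' removed together by the loop; with `unit = "case"` the winning case
#' alone is returned.
#'
#' @param outliers Data.frame of outlier records from [tukey_outliers()].
#' @param unit `"participant"` or `"case"`.
#' @return List with `participant_id`, `case_index` (the winning record's
#'   case), `severity`, `distance_beyond_fence`.
#' @export
select_removal <- function(outliers, unit = c("participant", "case")) {
  unit <- match.arg(unit)
  if (is.null(outliers) || nrow(outliers) == 0) {
    stop("cannot select a removal from an empty outlier list", call. = FALSE)
  }
  sev_rank <- ifelse(outliers$severity == "extreme", 0L, 1L)
  num <- suppressWarnings(as.integer(gsub("\\D", "", outliers$participant_id)))
  num[is.na(num)] <- .Machine$integer.max
  ord <- order(sev_rank, -outliers$distance_beyond_fence, num,
               outliers$participant_id)
  top <- outliers[ord[1], ]
  list(participant_id = top$participant_id,
       case_index = if (unit == "case") top$case_index else NA_character_,
       severity = top$severity,
       distance_beyond_fence = top$distance_beyond_fence)
}

# Full analysis of one retained-case set: fit, scores, outliers,
# assumptions and classification in one pass.
analyse_iteration <- function(m, lc) {
  model <- fit_discriminant(m, priors = lc$priors)
  scores <- discriminant_scores(model, m)
  outliers <- tukey_outliers(scores, m$group, m$participant_id,
                             case_index = m$case_index,
                             method = lc$quartile_method)
  bm <- box_m(m)
  norm <- normality_by_group(m)
  pred <- classify_cases(model, m)
  pred_cv <- loocv_classify(m, priors = lc$priors)
  report <- confusion_summary(m$group, pred, pred_cv)
  list(model = model, scores = scores, outliers = outliers, box_m = bm,
       normality = norm,
       group_mean_tests = group_mean_tests(m),
       wilks = wilks_overall(model),
       classification = report)
}

stop_conditions_met <- function(an, lc) {
  checks <- c(
    no_extreme_outliers = !any(an$outliers$severity == "extreme"),
    no_mild_outliers = nrow(an$outliers) == 0,
    box_m_pass = an$box_m$p >= lc$alpha,
    shapiro_pass = all(an$normality$sw_p >= lc$alpha))
  all(checks[lc$stop_requires])
}

make_record <- function(iter, an, n_before, removed) {
  list(iteration = iter,
       n_cases_before = n_before,
       outliers = an$outliers,
       removed_participant = removed,
       box_m_p = an$box_m$p,
       min_shapiro_p = min(an$normality$sw_p),
       accuracy_original = an$classification$original$overall_percent_correct,
       accuracy_cv = an$classification$cross_validated$overall_percent_correct)
}

as_phase_report <- function(an) {
  list(assumptions = list(box_m = an$box_m,
                          group_mean_tests = an$group_mean_tests,
                          wilks = an$wilks,
                          normality = an$normality),
       model = an$model,
       classification = an$classification,
       normality = an$normality,
       outliers = an$outliers)
}

#' Run the iterative outlier-classification feedback loop
#'
#' Iteration 0 analyses the full cohort (discriminant fit, score boxplot
#' outliers, Box's M, per-group normality, classification with
#' leave-one-out cross-validation). While any stopping condition fails and
#' outliers remain, the most pronounced outlier (extreme before mild,
#' largest distance beyond its fence) identifies a participant whose cases
#' are removed, and everything except the saved z-scores is recomputed on
#' the retained cases. The loop stops when all `stop_requires` conditions
#' hold (`assumptions_met`), when a removal would breach the minimum group
#' size (`min_group_size`), when no case lies beyond any fence but the
#' conditions still fail (`no_removable_outliers`), or at
#' `max_iterations`.
#'
#' @param samples A `biomarker_cohort` case table.
#' @param tc A [transform_config()].
#' @param lc A [loop_config()].
#' @return An object of class `loop_result`: `iterations` (list of
#'   per-iteration records), `classified_participants` (identifiers in
#'   removal order), `pre_report`, `post_report`, `terminated_by`, and
#'   `final_matrix` (retained cases).
#' @export
run_feedback_loop <- function(samples, tc = transform_config(),
                              lc = loop_config()) {
  m_full <- build_matrix(samples, tc)
  max_iter <- if (is.null(lc$max_iterations)) nrow(m_full$X) else lc$max_iterations
  m <- m_full
  iterations <- list()
  removed_participants <- character(0)
  terminated_by <- "max_iterations"
  pre_report <- NULL

  for (iter in seq.int(0L, max_iter)) {
    an <- analyse_iteration(m, lc)
    if (iter == 0L) pre_report <- as_phase_report(an)
    n_before <- nrow(m$X)
    if (stop_conditions_met(an, lc)) {
      iterations[[length(iterations) + 1L]] <-
        make_record(iter, an, n_before, NA_character_)
      terminated_by <- "assumptions_met"
      break
    }
    if (nrow(an$outliers) == 0L) {
      iterations[[length(iterations) + 1L]] <-
        make_record(iter, an, n_before, NA_character_)
      terminated_by <- "no_removable_outliers"
      break
    }
    if (iter == max_iter) {
      iterations[[length(iterations) + 1L]] <-
        make_record(iter, an, n_before, NA_character_)
      terminated_by <- "max_iterations"
      break
    }
    sel <- select_removal(an$outliers, lc$removal_unit)
    drop <- if (lc$removal_unit == "participant") {
      m$participant_id == sel$participant_id
    } else {
      m$case_index == sel$case_index
    }
    sizes_after <- table(factor(m$group[!drop], levels = c(1L, 2L)))
    if (any(sizes_after < lc$min_group_cases)) {
      iterations[[length(iterations) + 1L]] <-
        make_record(iter, an, n_before, NA_character_)
      terminated_by <- "min_group_size"
      break
    }
    iterations[[length(iterations) + 1L]] <-
      make_record(iter, an, n_before, sel$participant_id)
    removed_participants <- c(removed_participants, sel$participant_id)
    m <- subset_matrix(m, !drop)
  }

  post_an <- analyse_iteration(m, lc)
  structure(list(iterations = iterations,
                 classified_participants = removed_participants,
                 pre_report = pre_report,
                 post_report = as_phase_report(post_an),
                 terminated_by = terminated_by,
                 final_matrix = m),
            class = "loop_result")
}

#' @export
print.loop_result <- function(x, ...) {
  n_rem <- length(x$classified_participants)
  cat(sprintf("Iterative DFA classification loop: %d iteration(s), %d participant(s) removed\n",
              length(x$iterations), n_rem))
  if (n_rem > 0) {
    cat("  removal order:", paste(x$classified_participants, collapse = ", "), "\n")
  }
  cat(sprintf("  terminated by: %s\n", x$terminated_by))
  cat(sprintf("  Box's M p: %.4g (pre) -> %.4g (post)\n",
              x$pre_report$assumptions$box_m$p,
              x$post_report$assumptions$box_m$p))
  cat(sprintf("  overall %% correct (cross-validated): %.1f (pre) -> %.1f (post)\n",
              x$pre_report$classification$cross_validated$overall_percent_correct,
              x$post_report$classification$cross_validated$overall_percent_correct))
  invisible(x)
}

#' Write the full pre/post report set for a loop result
#'
#' Writes, for both the pre-classification and post-classification phases,
#' the normality, Box's M, group-mean-test, overall Wilks, standardized
#' coefficient and classification tables, plus an iteration log (one row
#' per iteration) and a machine-readable JSON run summary. Re-running on
#' the same result produces byte-identical files.
#'
#' @param result A `loop_result`.
#' @param directory Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_reports <- function(result, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(directory)) {
      stop(sprintf("cannot create report directory: %s", directory),
           call. = FALSE)
    }
  }
  fp <- function(...) file.path(directory, ...)
  phase <- function(rep, prefix) {
    write_normality_tsv(rep$normality, fp(paste0(prefix, "_normality.tsv")))
    write_box_m_tsv(rep$assumptions$box_m, fp(paste0(prefix, "_box_m.tsv")))
    write_group_mean_tests_tsv(rep$assumptions$group_mean_tests,
                               fp(paste0(prefix, "_group_mean_tests.tsv")))
    write_wilks_tsv(rep$assumptions$wilks, fp(paste0(prefix, "_wilks.tsv")))
    write_coefficients_tsv(rep$model, fp(paste0(prefix, "_coefficients.tsv")))
    write_classification_tsv(rep$classification,
                             fp(paste0(prefix, "_classification.tsv")))
    if (nrow(rep$outliers) > 0) {
      utils::write.csv(rep$outliers, fp(paste0(prefix, "_outliers.csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  phase(result$pre_report, "pre")
  phase(result$post_report, "post")

  log_rows <- do.call(rbind, lapply(result$iterations, function(r) {
    data.frame(iteration = r$iteration, n_cases_before = r$n_cases_before,
               n_outliers = nrow(r$outliers),
               n_extreme = sum(r$outliers$severity == "extreme"),
               removed_participant = ifelse(is.na(r$removed_participant), "",
                                            r$removed_participant),
               box_m_p = signif(r$box_m_p, 6),
               min_shapiro_p = signif(r$min_shapiro_p, 6),
               accuracy_original = r$accuracy_original,
               accuracy_cv = r$accuracy_cv, stringsAsFactors = FALSE)
  }))
  utils::write.csv(log_rows, fp("iteration_log.csv"), row.names = FALSE,
                   quote = FALSE)

  summary <- list(
    terminated_by = result$terminated_by,
    n_iterations = length(result$iterations),
    classified_participants = result$classified_participants,
    n_cases_pre = result$iterations[[1]]$n_cases_before,
    n_cases_post = nrow(result$final_matrix$X),
    box_m_p_pre = result$pre_report$assumptions$box_m$p,
    box_m_p_post = result$post_report$assumptions$box_m$p,
    accuracy_cv_pre =
      result$pre_report$classification$cross_validated$overall_percent_correct,
    accuracy_cv_post =
      result$post_report$classification$cross_validated$overall_percent_correct,
    standardized_coefficients_post =
      as.list(result$post_report$model$standardized_coefficients))
  jsonlite::write_json(summary, fp("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(directory)
}
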