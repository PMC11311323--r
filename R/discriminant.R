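#' Fit a two-group canonical discriminant function
#'
#' Solves the canonical eigenproblem \eqn{W^{-1}B\,b = \lambda b} with
#' \eqn{W} the within-group and \eqn{B} the between-group SSCP matrix, and
#' scales the leading eigenvector so the pooled within-group variance of
#' the discriminant scores is 1:
#' \eqn{b^\top \frac{W}{N - g} b = 1}. The constant \eqn{b_0} centers the
#' scores so their size-weighted mean over all cases is 0, and the sign is
#' oriented so the patient-group (code 1) centroid is positive. Fisher
#' linear classification functions
#' \eqn{f_j(x) = \bar{x}_j^\top S^{-1} x
#'   - \tfrac{1}{2}\bar{x}_j^\top S^{-1}\bar{x}_j + \ln \pi_j}
#' (with \eqn{S} the pooled covariance) are attached for classification.
#'
#' @param m A `cohort_matrix` with exactly two groups, each holding at
#'   least p + 1 cases.
#' @param priors `"equal"` (default) or `"proportional"` (to group sizes).
#' @return An object of class `discriminant_model` with elements
#'   `eigenvalue`, `raw_coefficients`, `constant`,
#'   `standardized_coefficients`, `group_centroids`, `group_means`,
#'   `pooled_covariance`, `priors`, `classification_functions`
#'   (list with `coefficients` p x g and `constants`), plus `N`, `p`, `g`
#'   and `variable_names`.
#' @export
fit_discriminant <- function(m, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  gl <- sort(unique(m$group))
  if (length(gl) != 2L) {
    stop("the canonical discriminant fit supports exactly two groups",
         call. = FALSE)
  }
  p <- ncol(m$X)
  idx <- split(seq_along(m$group), m$group)
  n <- vapply(idx, length, integer(1))
  if (any(n < p + 1L)) {
    stop(sprintf("each group needs at least p + 1 = %d cases to fit", p + 1L),
         call. = FALSE)
  }
  N <- nrow(m$X)
  g <- 2L
  means <- lapply(idx, function(i) colMeans(m$X[i, , drop = FALSE]))
  grand <- colMeans(m$X)
  W <- Reduce(`+`, lapply(idx, function(i) {
    Xi <- sweep(m$X[i, , drop = FALSE], 2, colMeans(m$X[i, , drop = FALSE]))
    crossprod(Xi)
  }))
  check_nonsingular(W / (N - g), "pooled within-group")
  B <- Reduce(`+`, Map(function(mu, nj) nj * tcrossprod(mu - grand), means, n))

  # Two-group closed form: the canonical direction is W^{-1}(mean1 - mean2).
  S <- W / (N - g)
  delta <- means[[1]] - means[[2]]
  if (max(abs(delta)) < 1e-12 * max(abs(m$X), 1e-300)) {
    # degenerate case: coincident group means carry no separation; any
    # direction is canonical with eigenvalue 0 - use the first variable
    d <- c(1, rep(0, p - 1))
  } else {
    d <- solve(W, delta)
  }
  scale_fac <- sqrt(as.numeric(t(d) %*% S %*% d))
  b <- d / scale_fac
  eigenvalue <- as.numeric(t(b) %*% B %*% b) / as.numeric(t(b) %*% W %*% b)
  if (sum(b * (means[[1]] - grand)) < 0) b <- -b  # patient centroid positive
  b0 <- -sum(b * grand)

  prior_vec <- if (priors == "equal") c(0.5, 0.5) else n / N
  names(prior_vec) <- gl
  Sinv_means <- vapply(means, function(mu) solve(S, mu), numeric(p))
  cf_const <- vapply(seq_len(2), function(j) {
    -0.5 * sum(means[[j]] * Sinv_means[, j]) + log(prior_vec[j])
  }, numeric(1))
  centroids <- vapply(means, function(mu) b0 + sum(b * mu), numeric(1))

  structure(list(eigenvalue = eigenvalue,
                 raw_coefficients = stats::setNames(b, colnames(m$X)),
                 constant = b0,
                 standardized_coefficients =
                   stats::setNames(b * sqrt(diag(S)), colnames(m$X)),
                 group_centroids = stats::setNames(centroids, gl),
                 group_means = means,
                 pooled_covariance = S,
                 priors = prior_vec,
                 prior_mode = priors,
                 classification_functions = list(coefficients = Sinv_means,
                                                 constants = cf_const),
                 group_levels = gl, group_sizes = n,
                 N = N, p = p, g = g,
                 variable_names = m$variable_names),
            class = "discriminant_model")
}

#' Standardized canonical discriminant function coefficients
#'
#' Raw coefficients scaled by the pooled within-group standard deviation of
#' each variable: \eqn{b_i^{std} = b_i \sqrt{S_{ii}}}. Their magnitudes
#' rank the variables' contributions to the discriminant score.
#'
#' @param model A fitted `discriminant_model`.
#' @return Named p-vector of standardized coefficients.
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "discriminant_model"))
  model$standardized_coefficients
}

check_compatible <- function(model, m) {
  if (ncol(m$X) != model$p ||
      !identical(unname(colnames(m$X)), unname(names(model$raw_coefficients)))) {
    stop("matrix variables do not match the fitted model", call. = FALSE)
  }
}

#' Discriminant scores for each case
#'
#' \eqn{score_i = b_0 + b^\top x_i}.
#'
#' @param model A fitted `discriminant_model`.
#' @param m A `cohort_matrix` on the same variables.
#' @return Numeric vector of per-case scores.
#' @export
discriminant_scores <- function(model, m) {
  stopifnot(inherits(model, "discriminant_model"))
  check_compatible(model, m)
  as.numeric(model$constant + m$X %*% model$raw_coefficients)
}

#' Classify cases with the fitted Fisher classification functions
#'
#' Each case is assigned to the group whose classification function is
#' largest; with equal priors this is the smaller-Mahalanobis-distance
#' rule. Exact ties go to the lower-coded group (patients = 1).
#'
#' @param model A fitted `discriminant_model`.
#' @param m A `cohort_matrix` on the same variables.
#' @return Integer vector of predicted group codes.
#' @export
classify_cases <- function(model, m) {
  stopifnot(inherits(model, "discriminant_model"))
  check_compatible(model, m)
  f <- m$X %*% model$classification_functions$coefficients
  f <- sweep(f, 2, model$classification_functions$constants, `+`)
  # ties (to working precision) go to the lower-coded group (patients = 1)
  scale <- pmax(abs(f[, 1]), abs(f[, 2]), 1)
  pick <- ifelse(f[, 2] - f[, 1] > 1e-9 * scale, 2L, 1L)
  model$group_levels[pick]
}

#' Leave-one-out cross-validated classification
#'
#' Each case is classified by classification functions derived from all
#' cases other than that case: group means and the pooled covariance are
#' refit on the remaining N - 1 cases (proportional priors, when selected,
#' are also recomputed from the reduced sizes).
#'
#' @param m A `cohort_matrix` with each group holding at least p + 2 cases.
#' @param priors `"equal"` or `"proportional"`.
#' @return Integer vector of cross-validated predicted group codes.
#' @export
loocv_classify <- function(m, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  sizes <- table(m$group)
  p <- ncol(m$X)
  if (any(sizes < p + 2L)) {
    stop(sprintf("LOOCV needs at least p + 2 = %d cases per group", p + 2L),
         call. = FALSE)
  }
  N <- nrow(m$X)
  pred <- integer(N)
  for (i in seq_len(N)) {
    mi <- subset_matrix(m, -i)
    fit <- tryCatch(fit_discriminant(mi, priors = priors),
                    error = function(e) {
      stop(sprintf("leave-one-out fit without case '%s' failed: %s",
                   m$case_index[i], conditionMessage(e)), call. = FALSE)
    })
    pred[i] <- classify_cases(fit, subset_matrix(m, i))
  }
  pred
}

#' Confusion summary for original and cross-validated predictions
#'
#' Counts and row percentages (one decimal) per true group, plus the
#' overall percent correctly classified, for the original-fit pass and
#' (optionally) the leave-one-out cross-validated pass.
#'
#' @param true_groups Integer vector of true group codes (1/2).
#' @param predicted_original Predictions from the model fit on all cases.
#' @param predicted_cv Optional cross-validated predictions.
#' @return An object of class `classification_report`: for each pass a
#'   `counts` g x g matrix (true x predicted), `row_percents`, and
#'   `overall_percent_correct`.
#' @export
confusion_summary <- function(true_groups, predicted_original,
                              predicted_cv = NULL) {
  check_labels <- function(x, what) {
    if (!all(x %in% c(1L, 2L))) {
      stop(sprintf("%s contains a group label outside {1, 2}", what),
           call. = FALSE)
    }
  }
  true_groups <- as.integer(true_groups)
  predicted_original <- as.integer(predicted_original)
  check_labels(true_groups, "true_groups")
  check_labels(predicted_original, "predicted_original")
  if (length(predicted_original) != length(true_groups)) {
    stop("true and predicted vectors must have equal length", call. = FALSE)
  }
  one_pass <- function(pred) {
    counts <- table(factor(true_groups, levels = 1:2),
                    factor(pred, levels = 1:2))
    counts <- unclass(counts)
    dimnames(counts) <- list(true = c("Patient", "Volunteer"),
                             predicted = c("Patient", "Volunteer"))
    rp <- round(100 * counts / rowSums(counts), 1)
    overall <- round(100 * sum(diag(counts)) / sum(counts), 1)
    list(counts = counts, row_percents = rp,
         overall_percent_correct = overall)
  }
  res <- list(original = one_pass(predicted_original))
  if (!is.null(predicted_cv)) {
    predicted_cv <- as.integer(predicted_cv)
    check_labels(predicted_cv, "predicted_cv")
    if (length(predicted_cv) != length(true_groups)) {
      stop("true and predicted vectors must have equal length", call. = FALSE)
    }
    res$cross_validated <- one_pass(predicted_cv)
  }
  class(res) <- "classification_report"
  res
}

tukey_hinges <- function(x) {
  fn <- stats::fivenum(x)
  c(q1 = fn[2], q3 = fn[4])
}

quartiles_by <- function(x, method) {
  if (method == "hinges") {
    tukey_hinges(x)
  } else {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    c(q1 = q[1], q3 = q[2])
  }
}

#' Tukey-fence outlier detection on grouped discriminant scores
#'
#' Per group, quartiles are computed as Tukey hinges (the boxplot
#' convention; configurable to linear-interpolation quantiles) and cases
#' beyond `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged mild, beyond the
#' 3 IQR fences extreme. `distance_beyond_fence` measures how far a mild
#' case lies beyond the inner fence, and an extreme case beyond the outer
#' fence, so distances compare like with like within a severity class.
#' With a degenerate IQR of 0, values equal to the median are never
#' flagged and any differing value is flagged mild with distance
#' `|score - median|`.
#'
#' @param scores Numeric vector of discriminant scores.
#' @param group Integer group codes aligned with `scores`.
#' @param participant_id Participant identifiers aligned with `scores`.
#' @param case_index Optional case identifiers (defaults to position).
#' @param method Quartile method: `"hinges"` (default) or `"quantile"`.
#' @return Data.frame of outlier records sorted extreme-first then by
#'   descending `distance_beyond_fence`: columns `case_index`,
#'   `participant_id`, `group`, `score`, `severity`
#'   (`"mild"`/`"extreme"`), `distance_beyond_fence`. Zero rows when no
#'   case lies beyond a fence.
#' @export
tukey_outliers <- function(scores, group, participant_id,
                           case_index = NULL,
                           method = c("hinges", "quantile")) {
  method <- match.arg(method)
  if (is.null(case_index)) case_index <- as.character(seq_along(scores))
  sizes <- table(group)
  if (any(sizes < 4L)) {
    stop("Tukey fences need at least 4 scores per group", call. = FALSE)
  }
  recs <- list()
  for (g in sort(unique(group))) {
    sel <- which(group == g)
    x <- scores[sel]
    q <- quartiles_by(x, method)
    iqr <- q["q3"] - q["q1"]
    if (iqr == 0) {
      med <- stats::median(x)
      dev <- abs(x - med)
      out <- which(dev > 0)
      if (length(out) > 0) {
        recs[[length(recs) + 1L]] <- data.frame(
          case_index = case_index[sel][out],
          participant_id = participant_id[sel][out],
          group = g, score = x[out], severity = "mild",
          distance_beyond_fence = dev[out], stringsAsFactors = FALSE)
      }
      next
    }
    lo_mild <- q["q1"] - 1.5 * iqr; hi_mild <- q["q3"] + 1.5 * iqr
    lo_ext <- q["q1"] - 3 * iqr;    hi_ext <- q["q3"] + 3 * iqr
    beyond_mild <- pmax(lo_mild - x, x - hi_mild, 0)
    beyond_ext <- pmax(lo_ext - x, x - hi_ext, 0)
    out <- which(beyond_mild > 0)
    if (length(out) > 0) {
      sev <- ifelse(beyond_ext[out] > 0, "extreme", "mild")
      dist <- ifelse(sev == "extreme", beyond_ext[out], beyond_mild[out])
      recs[[length(recs) + 1L]] <- data.frame(
        case_index = case_index[sel][out],
        participant_id = participant_id[sel][out],
        group = g, score = x[out], severity = sev,
        distance_beyond_fence = dist, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) {
    return(data.frame(case_index = character(0), participant_id = character(0),
                      group = integer(0), score = numeric(0),
                      severity = character(0),
                      distance_beyond_fence = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out[order(out$severity != "extreme", -out$distance_beyond_fence,
            out$participant_id), , drop = FALSE]
}

#' Write a classification report to TSV
#'
#' Mirrors the "Classification Results" layout including the percent
#' footnotes.
#'
#' @param report A `classification_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(report, path) {
  lines <- c("Pass\tMetric\tGrouping\tPatient\tVolunteer\tTotal")
  fmt_pass <- function(pass, label) {
    for (g in 1:2) {
      gname <- c("Patient", "Volunteer")[g]
      lines <<- c(lines, sprintf("%s\tCount\t%s\t%d\t%d\t%d", label, gname,
                                 pass$counts[g, 1], pass$counts[g, 2],
                                 sum(pass$counts[g, ])))
    }
    for (g in 1:2) {
      gname <- c("Patient", "Volunteer")[g]
      lines <<- c(lines, sprintf("%s\t%%\t%s\t%.1f\t%.1f\t100.0", label, gname,
                                 pass$row_percents[g, 1],
                                 pass$row_percents[g, 2]))
    }
  }
  fmt_pass(report$original, "Original")
  foot <- sprintf("a. %.1f%% of original grouped cases correctly classified.",
                  report$original$overall_percent_correct)
  if (!is.null(report$cross_validated)) {
    fmt_pass(report$cross_validated, "Cross-validated")
    foot <- c(foot,
      "b. Cross validation is done only for those cases in the analysis. In cross validation, each case is classified by the functions derived from all cases other than that case.",
      sprintf("c. %.1f%% of cross-validated grouped cases correctly classified.",
              report$cross_validated$overall_percent_correct))
  }
  writeLines(c(lines, foot), path)
  invisible(path)
}

#' Write standardized discriminant coefficients to TSV
#'
#' @param model A fitted `discriminant_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients_tsv <- function(model, path) {
  out <- data.frame(Variable = model$variable_names,
                    `Function 1` = round(unname(model$standardized_coefficients), 3),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
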