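test_that("the canonical fit matches the two-group closed form and its invariants", {
  set.seed(301)
  for (r in 1:20) {
    m <- random_groups(15 + r %% 6, 12 + r %% 5, shift = 0.8)
    fit <- fit_discriminant(m)
    S <- fit$pooled_covariance
    d <- solve(S, fit$group_means[[1]] - fit$group_means[[2]])
    cosang <- abs(sum(fit$raw_coefficients * d) /
                  sqrt(sum(fit$raw_coefficients^2) * sum(d^2)))
    expect_gte(cosang, 1 - 1e-8)

    sc <- discriminant_scores(fit, m)
    # imposed normalization: pooled within-group score variance 1,
    # size-weighted mean 0, patient centroid positive
    ssw <- sum(unlist(tapply(sc, m$group, function(v) (v - mean(v))^2)))
    expect_equal(ssw / (length(sc) - 2), 1, tolerance = 1e-10)
    expect_equal(mean(sc), 0, tolerance = 1e-10)
    expect_gt(fit$group_centroids[["1"]], 0)
    # Wilks/eigenvalue link to the covariance module
    expect_equal(wilks_overall(fit)$lambda * (1 + fit$eigenvalue), 1,
                 tolerance = 1e-10)
  }

  # identical group means: no separation
  set.seed(302)
  X <- matrix(rnorm(90), ncol = 3)
  m0 <- mk_matrix(rbind(X, X + 0), rep(1:2, each = 30))
  m0$X <- rbind(X, X)
  fit0 <- fit_discriminant(m0)
  expect_lt(fit0$eigenvalue, 1e-10)
})

test_that("the fitted direction agrees with an established LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(303)
  m <- random_groups(25, 30)
  fit <- fit_discriminant(m)
  ml <- MASS::lda(m$X, grouping = m$group)
  cosang <- abs(sum(fit$raw_coefficients * ml$scaling) /
                sqrt(sum(fit$raw_coefficients^2) * sum(ml$scaling^2)))
  expect_gte(cosang, 1 - 1e-10)
})

test_that("standardized coefficients rescale by pooled within-group sd", {
  set.seed(304)
  m <- random_groups(20, 20)
  m$X <- sweep(m$X, 2, c(1, 4, 0.2), `*`)  # unequal scales
  fit <- fit_discriminant(m)
  expect_equal(standardized_coefficients(fit),
               fit$raw_coefficients * sqrt(diag(fit$pooled_covariance)),
               tolerance = 1e-12)
})

test_that("scores and classification follow the model algebra", {
  set.seed(305)
  m <- random_groups(18, 22)
  fit <- fit_discriminant(m)
  sc <- discriminant_scores(fit, m)
  expect_equal(sc, as.numeric(fit$constant + m$X %*% fit$raw_coefficients),
               tolerance = 1e-12)
  # a case at the size-weighted grand centroid scores 0
  mg <- m; mg$X <- matrix(colMeans(m$X), 1,
                          dimnames = list(NULL, colnames(m$X)))
  mg$group <- 1L; mg$case_index <- "g"; mg$participant_id <- "g"
  expect_equal(discriminant_scores(fit, mg), 0, tolerance = 1e-10)

  # equal priors: agreement with the brute-force Mahalanobis rule
  pred <- classify_cases(fit, m)
  Sinv <- solve(fit$pooled_covariance)
  maha <- sapply(1:2, function(g) {
    dd <- sweep(m$X, 2, fit$group_means[[g]])
    rowSums((dd %*% Sinv) * dd)
  })
  expect_equal(pred, c(1L, 2L)[apply(maha, 1, which.min)])

  # case at a group mean goes to that group; exact midpoint breaks to group 1
  mv <- m
  mv$X <- rbind(fit$group_means[[2]],
                (fit$group_means[[1]] + fit$group_means[[2]]) / 2)
  colnames(mv$X) <- colnames(m$X)
  mv$group <- c(2L, 1L); mv$case_index <- c("a", "b")
  mv$participant_id <- c("a", "b")
  expect_equal(classify_cases(fit, mv), c(2L, 1L))

  # variable mismatch is an error
  bad <- m; colnames(bad$X) <- c("x", "y", "z")
  expect_error(discriminant_scores(fit, bad), "do not match")
})

test_that("LOOCV equals a naive per-case refit oracle", {
  # oracle: means, pooled covariance and Fisher functions recomputed from
  # scratch per held-out case with plain cov(), no package fit involved
  naive_cv <- function(m) {
    N <- nrow(m$X)
    out <- integer(N)
    for (i in seq_len(N)) {
      Xr <- m$X[-i, , drop = FALSE]; gr <- m$group[-i]
      mu <- lapply(1:2, function(g) colMeans(Xr[gr == g, , drop = FALSE]))
      n <- table(factor(gr, 1:2)); Nr <- sum(n)
      Sp <- ((n[1] - 1) * cov(Xr[gr == 1, ]) +
             (n[2] - 1) * cov(Xr[gr == 2, ])) / (Nr - 2)
      f <- sapply(1:2, function(g) {
        w <- solve(Sp, mu[[g]])
        sum(w * m$X[i, ]) - 0.5 * sum(w * mu[[g]]) + log(0.5)
      })
      out[i] <- which.max(f)
    }
    out
  }
  set.seed(306)
  for (r in 1:5) {
    m <- random_groups(15, 15, shift = 0.6)
    expect_equal(loocv_classify(m), naive_cv(m))
  }

  # tight, well-separated clusters: cross-validated = original predictions
  set.seed(307)
  msep <- random_groups(12, 12, shift = 10)
  fit <- fit_discriminant(msep)
  expect_equal(loocv_classify(msep), unname(classify_cases(fit, msep)))

  # overfitting tendency: cv accuracy <= resubstitution accuracy on
  # small overlapping samples in at least 70% of seeds
  set.seed(308)
  hits <- 0L
  for (r in 1:50) {
    m <- random_groups(8, 8, shift = 0.7)
    fit <- fit_discriminant(m)
    acc_orig <- mean(classify_cases(fit, m) == m$group)
    acc_cv <- mean(loocv_classify(m) == m$group)
    if (acc_cv <= acc_orig) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.7)
})

test_that("confusion summaries compute counts, row percents and overall accuracy", {
  truth <- rep(1:2, c(4, 6))
  rep_perf <- confusion_summary(truth, truth, truth)
  expect_equal(rep_perf$original$overall_percent_correct, 100)
  expect_equal(unname(diag(rep_perf$original$counts)), c(4, 6))
  expect_equal(sum(rep_perf$original$counts) -
               sum(diag(rep_perf$original$counts)), 0)
  expect_equal(unname(rowSums(rep_perf$cross_validated$row_percents)),
               c(100, 100))
  expect_error(confusion_summary(c(1, 3), c(1, 1)), "outside")
  expect_error(confusion_summary(c(1, 2), c(1, 1, 2)), "equal length")
})

test_that("Tukey fences flag outliers like a brute-force hinge oracle", {
  sc <- c(1:9, 100)
  out <- tukey_outliers(sc, rep(1L, 10), as.character(1:10))
  expect_equal(nrow(out), 1L)
  expect_equal(out$severity, "extreme")
  expect_equal(out$participant_id, "10")

  hinge_oracle <- function(x) {
    s <- sort(x); n <- length(s)
    lower <- s[1:ceiling(n / 2)]; upper <- s[floor(n / 2 + 1):n]
    c(median(lower), median(upper))
  }
  set.seed(309)
  for (r in 1:20) {
    x <- rt(30 + r, df = 3)
    g <- rep(1L, length(x))
    out <- tukey_outliers(x, g, as.character(seq_along(x)))
    q <- hinge_oracle(x); iqr <- q[2] - q[1]
    expected <- which(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
    expect_setequal(out$participant_id, as.character(expected))
    if (nrow(out) > 0) {
      expect_true(all(out$distance_beyond_fence > 0))
      # extreme implies beyond the mild fence too
      ext <- out$severity == "extreme"
      expect_true(all(x[as.integer(out$participant_id[ext])] < q[1] - 3 * iqr |
                      x[as.integer(out$participant_id[ext])] > q[2] + 3 * iqr))
      # sorted extreme-first, then by descending distance within severity
      sev <- out$severity
      expect_true(all(diff(as.integer(factor(sev, c("extreme", "mild")))) >= 0))
      for (s in unique(sev)) {
        d <- out$distance_beyond_fence[sev == s]
        expect_true(all(diff(d) <= 1e-12))
      }
    }
  }

  # no values beyond the fences: empty record set
  expect_equal(nrow(tukey_outliers(seq(0, 1, length.out = 20), rep(1L, 20),
                                   as.character(1:20))), 0L)
  # degenerate IQR: equal-to-median never flagged, any other value mild
  xz <- c(rep(5, 9), 6)
  outz <- tukey_outliers(xz, rep(1L, 10), as.character(1:10))
  expect_equal(outz$severity, "mild")
  expect_equal(outz$distance_beyond_fence, 1)
})
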