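#' Per-group and pooled within-group covariance matrices
#'
#' Sample covariances \eqn{S_j} with divisor \eqn{n_j - 1} per group and the
#' pooled within-group covariance
#' \eqn{S = \sum_j (n_j - 1) S_j / (N - g)}.
#'
#' @param m A `cohort_matrix`.
#' @return List with `S` (named list of per-group covariances), `pooled`,
#'   `n` (group sizes) and `means` (per-group mean vectors).
#' @export
group_covariances <- function(m) {
  p <- ncol(m$X)
  gl <- sort(unique(m$group))
  idx <- split(seq_along(m$group), m$group)
  n <- vapply(idx, length, integer(1))
  if (any(n < p + 1L)) {
    stop(sprintf("each group needs at least p + 1 = %d cases for a full-rank covariance",
                 p + 1L), call. = FALSE)
  }
  S <- lapply(idx, function(i) stats::cov(m$X[i, , drop = FALSE]))
  for (j in seq_along(S)) check_nonsingular(S[[j]], sprintf("group %s", gl[j]))
  pooled <- Reduce(`+`, Map(function(s, nj) (nj - 1) * s, S, n)) /
    (sum(n) - length(n))
  check_nonsingular(pooled, "pooled")
  means <- lapply(idx, function(i) colMeans(m$X[i, , drop = FALSE]))
  list(S = S, pooled = pooled, n = n, means = means)
}

# Fails when the covariance is not positive-definite to working precision
# (relative tolerance 1e-12 on the log-determinant scale via Cholesky).
check_nonsingular <- function(S, label) {
  ok <- tryCatch({
    R <- chol(S)
    all(diag(R)^2 > 1e-12 * max(diag(S), 1e-300))
  }, error = function(e) FALSE)
  if (!ok) {
    stop(sprintf("singular covariance (%s)", label), call. = FALSE)
  }
  invisible(TRUE)
}

log_det <- function(S) {
  as.numeric(determinant(S, logarithm = TRUE)$modulus)
}

#' F approximation for Box's M
#'
#' Converts a Box's M statistic to an approximate F with
#' \deqn{c_1 = \left[\sum_j \frac{1}{n_j - 1} - \frac{1}{N - g}\right]
#'   \frac{2p^2 + 3p - 1}{6(p + 1)(g - 1)},\quad
#'   c_2 = \left[\sum_j \frac{1}{(n_j - 1)^2} - \frac{1}{(N - g)^2}\right]
#'   \frac{(p - 1)(p + 2)}{6(g - 1)},}
#' \eqn{df_1 = p(p+1)(g-1)/2} and \eqn{df_2 = (df_1 + 2)/|c_2 - c_1^2|}.
#' When \eqn{c_2 > c_1^2}, \eqn{F = M/b} with
#' \eqn{b = df_1 / (1 - c_1 - df_1/df_2)}; otherwise
#' \eqn{F = df_2 M / (df_1 (b - M))} with
#' \eqn{b = df_2 / (1 - c_1 + 2/df_2)}. The p-value is the upper tail of
#' \eqn{F(df_1, df_2)}.
#'
#' @param M Box's M statistic (>= 0).
#' @param group_sizes Integer vector of group case counts, each > p.
#' @param p Number of variables.
#' @return List with `F`, `df1`, `df2`, `p_value`, `c1`, `c2`, `branch`.
#' @export
box_m_f_approx <- function(M, group_sizes, p) {
  n <- as.numeric(group_sizes)
  g <- length(n)
  if (g < 2L) stop("Box's M needs at least two groups", call. = FALSE)
  if (any(n <= p)) {
    stop(sprintf("every group size must exceed p = %d", p), call. = FALSE)
  }
  if (M < 0) stop("Box's M statistic cannot be negative", call. = FALSE)
  N <- sum(n)
  c1 <- (sum(1 / (n - 1)) - 1 / (N - g)) * (2 * p^2 + 3 * p - 1) /
    (6 * (p + 1) * (g - 1))
  c2 <- (sum(1 / (n - 1)^2) - 1 / (N - g)^2) * (p - 1) * (p + 2) /
    (6 * (g - 1))
  df1 <- p * (p + 1) * (g - 1) / 2
  df2 <- (df1 + 2) / abs(c2 - c1^2)
  if (c2 > c1^2) {
    b <- df1 / (1 - c1 - df1 / df2)
    Fstat <- M / b
    branch <- "c2 > c1^2"
  } else {
    b <- df2 / (1 - c1 + 2 / df2)
    Fstat <- df2 * M / (df1 * (b - M))
    branch <- "c2 <= c1^2"
  }
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       c1 = c1, c2 = c2, branch = branch)
}

#' Box's M test of equality of group covariance matrices
#'
#' \deqn{M = (N - g)\ln|S_{pooled}| - \sum_j (n_j - 1)\ln|S_j|}
#' with natural logarithms, combined with the F approximation of
#' [box_m_f_approx()]. `M = 0` exactly when all group covariances are
#' identical.
#'
#' @param m A `cohort_matrix`.
#' @return An object of class `box_m_result`: `M`, `F`, `df1`, `df2`, `p`,
#'   `c1`, `c2`, `per_group_covariances`, `pooled_covariance`,
#'   `group_sizes`.
#' @export
box_m <- function(m) {
  gc <- group_covariances(m)
  N <- sum(gc$n)
  g <- length(gc$n)
  M <- (N - g) * log_det(gc$pooled) -
    sum(mapply(function(S, nj) (nj - 1) * log_det(S), gc$S, gc$n))
  M <- max(M, 0)  # guards tiny negative round-off when covariances coincide
  fa <- box_m_f_approx(M, gc$n, ncol(m$X))
  structure(list(M = M, F = fa$F, df1 = fa$df1, df2 = fa$df2,
                 p = fa$p_value, c1 = fa$c1, c2 = fa$c2, branch = fa$branch,
                 per_group_covariances = gc$S,
                 pooled_covariance = gc$pooled,
                 group_sizes = gc$n),
            class = "box_m_result")
}

#' Per-variable tests of equality of group means
#'
#' For each variable, Wilks' \eqn{\Lambda_i = SS_{within}/SS_{total}} and
#' \eqn{F = \frac{1 - \Lambda_i}{\Lambda_i}\cdot\frac{N - g}{g - 1}}
#' on \eqn{(g - 1, N - g)} degrees of freedom -- identical to the one-way
#' ANOVA F for that variable.
#'
#' @param m A `cohort_matrix`.
#' @return Data.frame with columns `variable`, `lambda`, `F`, `df1`, `df2`,
#'   `p`.
#' @export
group_mean_tests <- function(m) {
  g <- length(unique(m$group))
  N <- nrow(m$X)
  if (N <= g) stop("tests of group means need N > g cases", call. = FALSE)
  rows <- lapply(seq_len(ncol(m$X)), function(j) {
    x <- m$X[, j]
    sst <- sum((x - mean(x))^2)
    if (sst <= 0) {
      stop(sprintf("zero total variance in '%s'", m$variable_names[j]),
           call. = FALSE)
    }
    ssw <- sum(unlist(tapply(x, m$group, function(v) (v - mean(v))^2)))
    lambda <- ssw / sst
    Fstat <- ((1 - lambda) / lambda) * ((N - g) / (g - 1))
    data.frame(variable = m$variable_names[j], lambda = lambda, F = Fstat,
               df1 = g - 1L, df2 = N - g,
               p = stats::pf(Fstat, g - 1, N - g, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overall Wilks' lambda with Bartlett's chi-square
#'
#' From the discriminant eigenvalues \eqn{\lambda_m},
#' \eqn{\Lambda = \prod_m 1/(1 + \lambda_m)} and Bartlett's statistic
#' \eqn{\chi^2 = -(N - (p + g)/2 - 1)\ln\Lambda} on \eqn{p(g-1)} degrees of
#' freedom. For two groups there is exactly one nonzero eigenvalue and
#' \eqn{\Lambda = 1/(1 + \lambda)}.
#'
#' @param m A `cohort_matrix`, or a fitted `discriminant_model` (in which
#'   case `N`, `p`, `g` are taken from the fit).
#' @return List with `lambda` (Wilks), `chi_square`, `df`, `p`,
#'   `eigenvalues`.
#' @seealso [wilks_bartlett()] for the desk formula on a printed lambda.
#' @export
wilks_overall <- function(m) {
  if (inherits(m, "discriminant_model")) {
    model <- m
  } else {
    model <- fit_discriminant(m)
  }
  ev <- model$eigenvalue
  lambda <- prod(1 / (1 + ev))
  wb <- wilks_bartlett(lambda, N = model$N, p = model$p, g = model$g)
  c(wb, list(eigenvalues = ev))
}

#' Bartlett's chi-square for a given Wilks' lambda
#'
#' Desk version of the overall significance test: given a (possibly
#' printed) \eqn{\Lambda}, returns
#' \eqn{\chi^2 = -(N - (p + g)/2 - 1)\ln\Lambda} with \eqn{p(g-1)} df.
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param N Total case count.
#' @param p Number of variables.
#' @param g Number of groups.
#' @return List with `lambda`, `chi_square`, `df`, `p`.
#' @export
wilks_bartlett <- function(lambda, N, p, g) {
  if (lambda <= 0 || lambda > 1) {
    stop("Wilks' lambda must lie in (0, 1]", call. = FALSE)
  }
  chi <- -(N - (p + g) / 2 - 1) * log(lambda)
  df <- p * (g - 1)
  list(lambda = lambda, chi_square = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Write a Box's M test result to TSV
#'
#' Mirrors the "Test Results" layout (Box's M, F Approx., df1, df2, Sig.).
#'
#' @param bm A `box_m_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_box_m_tsv <- function(bm, path) {
  out <- data.frame(
    Statistic = c("Box's M", "F Approx.", "df1", "df2", "Sig."),
    Value = c(round(bm$M, 3), round(bm$F, 3), bm$df1, round(bm$df2, 3),
              signif(bm$p, 5)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-variable tests of equality of group means to TSV
#'
#' @param tab Output of [group_mean_tests()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_group_mean_tests_tsv <- function(tab, path) {
  out <- data.frame(Variable = tab$variable,
                    `Wilks' Lambda` = round(tab$lambda, 3),
                    F = round(tab$F, 3), df1 = tab$df1, df2 = tab$df2,
                    `Sig.` = signif(tab$p, 4),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the overall Wilks' lambda summary to TSV
#'
#' @param wo Output of [wilks_overall()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_wilks_tsv <- function(wo, path) {
  out <- data.frame(`Test of Function(s)` = 1L,
                    `Wilks' Lambda` = round(wo$lambda, 4),
                    `Chi-Square` = round(wo$chi_square, 4),
                    df = wo$df, `Sig.` = signif(wo$p, 4),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
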