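#' Shapiro-Wilk test of normality
#'
#' Standard Shapiro-Wilk W with Royston's p-value approximation; higher W
#' means closer to normal.
#'
#' @param series Numeric vector, 3 <= n <= 5000, nonconstant.
#' @return List with `statistic` (W) and `p`.
#' @export
shapiro_wilk <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3L || n > 5000L) {
    stop(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got n = %d)", n),
         call. = FALSE)
  }
  if (stats::sd(series) == 0) {
    stop("Shapiro-Wilk undefined for a zero-variance series", call. = FALSE)
  }
  ht <- stats::shapiro.test(series)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Lilliefors-corrected Kolmogorov-Smirnov test of normality
#'
#' Kolmogorov-Smirnov D against a normal distribution with mean and sd
#' estimated from the sample, with the Lilliefors significance correction.
#' Mirroring the reporting convention of the source software, the displayed
#' p-value is capped at 0.200 and flagged as a lower bound of the true
#' significance when the computed p exceeds it; the uncapped value is
#' retained in `p_raw`.
#'
#' @param series Numeric vector, n >= 4, nonconstant.
#' @return List with `statistic` (D), `p` (capped at 0.200), `p_raw`, and
#'   `lower_bound` (`TRUE` when the cap was applied).
#' @export
lilliefors_ks <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 4L) {
    stop("Lilliefors K-S requires n >= 4", call. = FALSE)
  }
  if (stats::sd(series) == 0) {
    stop("Lilliefors K-S undefined for a zero-variance series", call. = FALSE)
  }
  ht <- nortest::lillie.test(series)
  p_raw <- min(max(unname(ht$p.value), 0), 1)
  capped <- p_raw > 0.2
  list(statistic = unname(ht$statistic),
       p = if (capped) 0.2 else p_raw,
       p_raw = p_raw,
       lower_bound = capped)
}

#' Per-group tests of normality for every analysed variable
#'
#' One row per variable x group, in the layout of an SPSS "Tests of
#' Normality" table: Lilliefors-corrected Kolmogorov-Smirnov and
#' Shapiro-Wilk statistics with significance, df equal to the group case
#' count.
#'
#' @param m A `cohort_matrix`.
#' @return A data.frame with columns `variable`, `group` (1 = patient,
#'   2 = volunteer), `ks_statistic`, `ks_p` (capped at 0.200),
#'   `ks_lower_bound`, `sw_statistic`, `sw_p`, `df`.
#' @export
normality_by_group <- function(m) {
  sizes <- table(factor(m$group, levels = sort(unique(m$group))))
  if (any(sizes < 4L)) {
    stop(sprintf("each group needs >= 4 cases for normality testing (sizes: %s)",
                 paste(sizes, collapse = ", ")), call. = FALSE)
  }
  rows <- list()
  for (j in seq_len(ncol(m$X))) {
    for (g in sort(unique(m$group))) {
      x <- m$X[m$group == g, j]
      ks <- lilliefors_ks(x)
      sw <- shapiro_wilk(x)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = m$variable_names[j], group = g,
        ks_statistic = ks$statistic, ks_p = ks$p,
        ks_lower_bound = ks$lower_bound,
        sw_statistic = sw$statistic, sw_p = sw$p,
        df = length(x), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Normal Q-Q plot coordinates
#'
#' Pairs the sorted sample with standard-normal quantiles at Blom plotting
#' positions \eqn{(i - 3/8) / (n + 1/4)} (the source software's Q-Q
#' default); the position constants are configurable.
#'
#' @param series Numeric vector, n >= 2.
#' @param a,b Plotting position constants in \eqn{(i - a) / (n + b)}.
#' @return A data.frame with columns `theoretical` and `sample` (sorted
#'   input), of the same length as the input.
#' @export
qq_points <- function(series, a = 3 / 8, b = 1 / 4) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2L) stop("Q-Q coordinates need n >= 2", call. = FALSE)
  data.frame(theoretical = stats::qnorm((seq_len(n) - a) / (n + b)),
             sample = sort(series))
}

#' Write a per-group normality table to TSV
#'
#' Mirrors the "Tests of Normality" layout: Statistic, df, Sig. per test,
#' with `*` marking p-values reported at the 0.200 lower bound.
#'
#' @param tab Output of [normality_by_group()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_normality_tsv <- function(tab, path) {
  out <- data.frame(
    Variable = tab$variable,
    Grouping = ifelse(tab$group == 1L, "Patient", "Volunteer"),
    `KS Statistic` = round(tab$ks_statistic, 3),
    `KS df` = tab$df,
    `KS Sig.` = paste0(formatC(round(tab$ks_p, 3), format = "f", digits = 3),
                       ifelse(tab$ks_lower_bound, " *", "")),
    `SW Statistic` = round(tab$sw_statistic, 3),
    `SW df` = tab$df,
    `SW Sig.` = formatC(round(tab$sw_p, 3), format = "f", digits = 3),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
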