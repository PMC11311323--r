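#' Transformation configuration for the analysis matrix
#'
#' Controls the preprocessing pipeline applied by [build_matrix()]:
#' linear interpolation of missing values (LINT), per-variable log10
#' transformation, and pooled z-score standardization.
#'
#' @param log10_variables Character subset of `c("il6", "tnfa", "mpo")` to
#'   log10-transform after interpolation. The default logs MPO only,
#'   matching the convention of reporting `LINT(IL-6)`, `LINT(TNF-a)` and
#'   `MPO_LINT_Log10` as the analysed variables.
#' @param zscore_all If `TRUE` (default) every variable is z-scored over all
#'   cases pooled (both groups, divisor n-1) after transformation.
#' @param interpolation_ordering `"per_specimen"` (default) interpolates
#'   each variable within its (group x specimen) series in case order, so a
#'   missing plasma value is never interpolated from a serum neighbour;
#'   `"case_order"` interpolates straight down the case-ordered column.
#' @return An object of class `transform_config`.
#' @export
transform_config <- function(log10_variables = "mpo",
                             zscore_all = TRUE,
                             interpolation_ordering = c("per_specimen", "case_order")) {
  interpolation_ordering <- match.arg(interpolation_ordering)
  log10_variables <- as.character(log10_variables)
  extra <- setdiff(log10_variables, biomarker_names())
  if (length(extra) > 0) {
    stop(sprintf("log10_variables must be a subset of {il6, tnfa, mpo}; got: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  structure(list(log10_variables = log10_variables,
                 zscore_all = isTRUE(zscore_all),
                 interpolation_ordering = interpolation_ordering),
            class = "transform_config")
}

#' Linearly interpolate missing values in a series (LINT)
#'
#' Interior runs of missing values between observed neighbours at positions
#' `a < b` are filled with equally spaced values on the line through
#' `(a, x[a])` and `(b, x[b])`. Leading and trailing missing values are
#' filled by copying the nearest observed value, so the output is always
#' complete. Observed values are never changed.
#'
#' @param series Numeric vector, possibly containing `NA`.
#' @return Numeric vector of the same length with no missing values.
#' @examples
#' linear_interpolate(c(1, NA, 3))        # 1 2 3
#' linear_interpolate(c(10, NA, NA, 40))  # 10 20 30 40
#' @export
linear_interpolate <- function(series) {
  if (!is.numeric(series)) series <- as.numeric(series)
  if (all(is.na(series))) {
    stop("no observed values to interpolate from", call. = FALSE)
  }
  if (!anyNA(series)) return(series)
  as.numeric(zoo::na.approx(series, na.rm = FALSE, rule = 2))
}

#' Base-10 logarithm with strict positivity check
#'
#' @param series Numeric vector of strictly positive values.
#' @param variable Label used in error messages.
#' @return `log10(series)`.
#' @export
log10_transform <- function(series, variable = "value") {
  bad <- which(!is.na(series) & series <= 0)
  if (length(bad) > 0) {
    stop(sprintf("log10 transform of '%s' undefined: non-positive value at case %d (%g)",
                 variable, bad[1], series[bad[1]]), call. = FALSE)
  }
  log10(series)
}

#' Z-score standardization over the pooled sample
#'
#' Centers and scales to mean 0, sd 1 using the sample standard deviation
#' (divisor n-1) computed over all cases pooled, both groups together.
#'
#' @param series Numeric vector of length >= 2 with nonzero variance.
#' @return Standardized vector.
#' @export
zscore <- function(series) {
  if (length(series) < 2L) {
    stop("z-score needs at least 2 cases", call. = FALSE)
  }
  s <- stats::sd(series)
  if (!is.finite(s) || s <= 0) {
    stop("z-score undefined for a constant (zero-variance) series", call. = FALSE)
  }
  (series - mean(series)) / s
}

#' Assemble the case-by-variable analysis matrix
#'
#' Applies, in order: linear interpolation of missing concentrations (within
#' the ordering unit of the configuration), log10 transformation of the
#' configured variables, and pooled z-scoring of every variable. Case order
#' is never changed: row `i` of the matrix is case `i` of the input.
#'
#' @param samples A `biomarker_cohort` (or data.frame with columns
#'   `participant_id`, `group`, `specimen`, `il6`, `tnfa`, `mpo`).
#' @param tc A [transform_config()].
#' @return An object of class `cohort_matrix`: a list with `case_index`
#'   (participant_id + specimen), `participant_id`, `group`, `X`
#'   (cases x 3 numeric matrix, no missing entries), `variable_names`
#'   (report labels) and `transform` (the applied configuration).
#' @export
build_matrix <- function(samples, tc = transform_config()) {
  if (nrow(samples) == 0L) {
    stop("cannot build an analysis matrix from an empty sample list", call. = FALSE)
  }
  if (!inherits(tc, "transform_config")) {
    stop("tc must be a transform_config()", call. = FALSE)
  }
  group <- as.integer(samples$group)
  if (length(unique(group)) < 2L || any(table(group) < 2L)) {
    stop("analysis matrix needs at least 2 cases in each of 2 groups", call. = FALSE)
  }
  vars <- biomarker_names()
  X <- matrix(NA_real_, nrow = nrow(samples), ncol = length(vars),
              dimnames = list(NULL, vars))
  for (v in vars) {
    col <- as.numeric(samples[[v]])
    filled <- tryCatch({
      if (tc$interpolation_ordering == "per_specimen") {
        unit <- interaction(samples$group, samples$specimen, drop = TRUE)
        for (u in levels(unit)) {
          idx <- which(unit == u)
          col[idx] <- linear_interpolate(col[idx])
        }
        col
      } else {
        linear_interpolate(col)
      }
    }, error = function(e) {
      stop(sprintf("interpolation of '%s' failed: %s", v, conditionMessage(e)),
           call. = FALSE)
    })
    if (v %in% tc$log10_variables) filled <- log10_transform(filled, v)
    X[, v] <- filled
  }
  if (tc$zscore_all) {
    for (v in vars) X[, v] <- zscore(X[, v])
  }
  labels <- variable_labels(tc)
  structure(list(case_index = paste(samples$participant_id, samples$specimen, sep = ":"),
                 participant_id = as.character(samples$participant_id),
                 group = group,
                 X = X,
                 variable_names = labels,
                 transform = tc),
            class = "cohort_matrix")
}

# SPSS-style report labels, e.g. "Zscore: LINT(IL-6)" / "Zscore: (MPO_LINT_Log10)"
variable_labels <- function(tc) {
  pretty <- c(il6 = "IL-6", tnfa = "TNF-a", mpo = "MPO")
  vapply(biomarker_names(), function(v) {
    core <- if (v %in% tc$log10_variables) {
      sprintf("(%s_LINT_Log10)", pretty[[v]])
    } else {
      sprintf("LINT(%s)", pretty[[v]])
    }
    if (tc$zscore_all) paste0("Zscore: ", core) else core
  }, character(1))
}

#' Subset a cohort matrix by case
#'
#' Retains the given cases (logical or integer index), preserving order.
#' Transformed values are not recomputed: z-scores remain those of the full
#' pre-subset matrix, matching an analysis in which standardized variables
#' are saved once and cases are then filtered.
#'
#' @param m A `cohort_matrix`.
#' @param keep Logical or integer case selector.
#' @return A `cohort_matrix` with the retained cases.
#' @export
subset_matrix <- function(m, keep) {
  structure(list(case_index = m$case_index[keep],
                 participant_id = m$participant_id[keep],
                 group = m$group[keep],
                 X = m$X[keep, , drop = FALSE],
                 variable_names = m$variable_names,
                 transform = m$transform),
            class = "cohort_matrix")
}

#' Write a transformed analysis matrix to TSV
#'
#' @param m A `cohort_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(case = m$case_index, participant_id = m$participant_id,
                  group = m$group, m$X, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
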