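#' Configuration for the synthetic biomarker cohort generator
#'
#' Defines the data-generating process for a two-group (osteoarthritis
#' patients vs. healthy volunteers) biomarker cohort in which every
#' participant contributes paired plasma and serum specimens. Concentrations
#' of IL-6, TNF-alpha (pg/mL) and MPO (ng/mL) are drawn as
#' \eqn{10^{z}} with \eqn{z} multivariate normal on the log10 scale, so raw
#' marginals are log-normal (right-skewed). A participant's plasma and serum
#' draws share a common random effect; a configurable fraction of
#' participants is "contaminated" with a fixed log-scale mean shift, and
#' cells can be set missing at random.
#'
#' The default group means and covariances describe a clean cohort in which
#' MPO separates the groups most strongly, then TNF-alpha, then IL-6, with
#' a common within-group covariance (log10 sd 0.35, pairwise correlation
#' 0.3). Contamination and missingness default to 0; analyses that emulate
#' the full messy study cohort enable them explicitly.
#'
#' @param n_patients,n_volunteers Number of participants per group.
#' @param specimens_per_participant Specimens per participant (2 = paired
#'   plasma + serum; additional specimens are labelled `"specimen3"`, ...).
#' @param group_log_means List with elements `patient` and `volunteer`, each
#'   a length-3 numeric vector of log10-scale means for (il6, tnfa, mpo).
#' @param group_log_covariances List with elements `patient` and `volunteer`,
#'   each a symmetric positive-definite 3x3 covariance matrix on the log10
#'   scale.
#' @param within_participant_correlation Correlation in `[0, 1)` between a
#'   participant's specimen-level deviations on the log scale.
#' @param missing_rate Probability in `[0, 1)` that any single concentration
#'   cell is set missing.
#' @param contamination_rate Fraction in `[0, 1)` of participants (patients
#'   and volunteers pooled) whose log-scale means are shifted by
#'   `contamination_shift`; the planted count is
#'   `floor(contamination_rate * n_participants)`.
#' @param contamination_shift Length-3 log10-scale shift added to the means
#'   of contaminated participants. The default is five times the default
#'   patient-volunteer log10 contrast (0.15, 0.28, 0.45): contaminated
#'   participants are exaggerated versions of the group difference
#'   (early-OA-like elevation), the one direction a fitted discriminant
#'   cannot rotate away from.
#' @param drop_volunteer_cases Number of trailing volunteer cases to drop
#'   after generation (`TRUE` is taken as 1). With paired specimens,
#'   29 + 15 participants generate 58 + 30 cases; dropping 3 volunteer
#'   cases reproduces a 58/27 analysis split in which some volunteers
#'   contributed a single usable specimen.
#' @param seed Integer seed; identical configurations yield cell-identical
#'   cohorts.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_cohort()], [true_parameters()]
#' @export
generator_config <- function(n_patients = 29,
                             n_volunteers = 15,
                             specimens_per_participant = 2,
                             group_log_means = list(
                               patient   = c(il6 = 0.90, tnfa = 1.05, mpo = 2.05),
                               volunteer = c(il6 = 0.75, tnfa = 0.77, mpo = 1.60)),
                             group_log_covariances = default_log_covariances(),
                             within_participant_correlation = 0.4,
                             missing_rate = 0,
                             contamination_rate = 0,
                             contamination_shift = c(il6 = 0.75, tnfa = 1.40, mpo = 2.25),
                             drop_volunteer_cases = 0L,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_volunteers = as.integer(n_volunteers),
              specimens_per_participant = as.integer(specimens_per_participant),
              group_log_means = group_log_means,
              group_log_covariances = group_log_covariances,
              within_participant_correlation = within_participant_correlation,
              missing_rate = missing_rate,
              contamination_rate = contamination_rate,
              contamination_shift = contamination_shift,
              drop_volunteer_cases = as.integer(drop_volunteer_cases),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

#' @keywords internal
default_log_covariances <- function(sd = 0.35, rho = 0.3) {
  S <- sd^2 * ((1 - rho) * diag(3) + rho)
  dimnames(S) <- list(biomarker_names(), biomarker_names())
  list(patient = S, volunteer = S)
}

biomarker_names <- function() c("il6", "tnfa", "mpo")

validate_generator_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid generator configuration: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L) bad("n_patients", "must be >= 1")
  if (is.na(cfg$n_volunteers) || cfg$n_volunteers < 1L) bad("n_volunteers", "must be >= 1")
  if (is.na(cfg$specimens_per_participant) || cfg$specimens_per_participant < 1L)
    bad("specimens_per_participant", "must be >= 1")
  for (g in c("patient", "volunteer")) {
    mu <- cfg$group_log_means[[g]]
    if (is.null(mu) || length(mu) != 3L || anyNA(mu))
      bad("group_log_means", sprintf("needs a complete length-3 '%s' vector", g))
    S <- cfg$group_log_covariances[[g]]
    if (is.null(S) || !is.matrix(S) || any(dim(S) != 3L))
      bad("group_log_covariances", sprintf("needs a 3x3 '%s' matrix", g))
    if (max(abs(S - t(S))) > 1e-8 * max(abs(S)))
      bad("group_log_covariances", sprintf("'%s' matrix is not symmetric", g))
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) bad("group_log_covariances", sprintf("'%s' matrix is not positive-definite", g))
  }
  w <- cfg$within_participant_correlation
  if (!is.numeric(w) || is.na(w) || w < 0 || w >= 1)
    bad("within_participant_correlation", "must lie in [0, 1)")
  for (f in c("missing_rate", "contamination_rate")) {
    r <- cfg[[f]]
    if (!is.numeric(r) || is.na(r) || r < 0 || r >= 1) bad(f, "must lie in [0, 1)")
  }
  if (length(cfg$contamination_shift) != 3L || anyNA(cfg$contamination_shift))
    bad("contamination_shift", "must be a complete length-3 vector")
  if (is.na(cfg$drop_volunteer_cases) || cfg$drop_volunteer_cases < 0L)
    bad("drop_volunteer_cases", "must be a nonnegative count")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  invisible(cfg)
}

participant_ids <- function(cfg) {
  c(sprintf("P%02d", seq_len(cfg$n_patients)),
    sprintf("V%02d", seq_len(cfg$n_volunteers)))
}

specimen_labels <- function(k) {
  base <- c("plasma", "serum")
  if (k <= 2L) base[seq_len(k)] else c(base, sprintf("specimen%d", 3:k))
}

# Contaminated participants are drawn first, from their own RNG substream,
# so that true_parameters() can replay the selection without regenerating
# the concentration draws.
select_contaminated <- function(cfg) {
  n_total <- cfg$n_patients + cfg$n_volunteers
  k <- floor(cfg$contamination_rate * n_total)
  if (k == 0L) return(character(0))
  set.seed(cfg$seed)
  sort(sample(participant_ids(cfg), k))
}

#' Generate a synthetic biomarker cohort
#'
#' Draws one specimen-level case table according to a [generator_config()].
#' Cases appear in deterministic participant order (patients `P01`, `P02`,
#' ... then volunteers `V01`, ...), each participant contributing
#' `specimens_per_participant` consecutive rows (plasma first). Groups are
#' coded numerically: patients as 1, volunteers as 2.
#'
#' Within a participant, specimen draws share a common standard-normal
#' random effect \eqn{u} so that the log-scale specimen values are
#' \eqn{\mu_g + L^\top(\sqrt{\rho}\,u + \sqrt{1-\rho}\,e_s)} with
#' \eqn{LL^\top} the group covariance (Cholesky) and \eqn{\rho} the
#' within-participant correlation. Contaminated participants (selected
#' seed-deterministically, `floor(rate * n)` of them) have
#' `contamination_shift` added to their log-scale mean before
#' exponentiation. After value generation each cell is independently set
#' missing with probability `missing_rate`.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` of class `biomarker_cohort` with columns
#'   `participant_id`, `group` (1 = patient, 2 = volunteer), `specimen`,
#'   `il6`, `tnfa`, `mpo` (raw concentrations, `NA` when missing) and the
#'   generator truth flag `contaminated`.
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 7))
#' table(cohort$group)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  validate_generator_config(config)
  cfg <- config
  ids <- participant_ids(cfg)
  groups <- rep(c(1L, 2L), c(cfg$n_patients, cfg$n_volunteers))
  k <- cfg$specimens_per_participant
  specs <- specimen_labels(k)
  contaminated <- select_contaminated(cfg)

  set.seed(cfg$seed + 1L)
  rho <- cfg$within_participant_correlation
  L <- lapply(cfg$group_log_covariances, chol)
  n_cases <- length(ids) * k
  logval <- matrix(NA_real_, n_cases, 3L)
  r <- 0L
  for (i in seq_along(ids)) {
    gname <- if (groups[i] == 1L) "patient" else "volunteer"
    mu <- as.numeric(cfg$group_log_means[[gname]])
    if (ids[i] %in% contaminated) mu <- mu + as.numeric(cfg$contamination_shift)
    u <- stats::rnorm(3L)
    for (s in seq_len(k)) {
      e <- stats::rnorm(3L)
      z <- sqrt(rho) * u + sqrt(1 - rho) * e
      r <- r + 1L
      logval[r, ] <- mu + as.numeric(t(L[[gname]]) %*% z)
    }
  }
  cohort <- data.frame(participant_id = rep(ids, each = k),
                       group = rep(groups, each = k),
                       specimen = rep(specs, times = length(ids)),
                       il6 = 10^logval[, 1], tnfa = 10^logval[, 2],
                       mpo = 10^logval[, 3],
                       contaminated = rep(ids %in% contaminated, each = k),
                       stringsAsFactors = FALSE)

  if (cfg$missing_rate > 0) {
    cells <- matrix(stats::runif(nrow(cohort) * 3L) < cfg$missing_rate,
                    ncol = 3L)
    for (j in seq_len(3L)) {
      cohort[[biomarker_names()[j]]][cells[, j]] <- NA_real_
    }
  }
  if (cfg$drop_volunteer_cases > 0L) {
    nd <- cfg$drop_volunteer_cases
    nvc <- sum(cohort$group == 2L)
    if (nd >= nvc) {
      stop("drop_volunteer_cases would remove every volunteer case", call. = FALSE)
    }
    cohort <- cohort[seq_len(nrow(cohort) - nd), , drop = FALSE]
    rownames(cohort) <- NULL
  }
  attr(cohort, "config") <- cfg
  class(cohort) <- c("biomarker_cohort", "data.frame")
  cohort
}

#' True generating parameters of a synthetic cohort
#'
#' Returns the exact per-group log10-scale means and covariances used by
#' [generate_cohort()] for a configuration, together with the
#' seed-deterministic list of contaminated participants, for
#' parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @return A list with elements `group_log_means`, `group_log_covariances`
#'   and `contaminated` (sorted participant ids).
#' @export
true_parameters <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  validate_generator_config(config)
  list(group_log_means = config$group_log_means,
       group_log_covariances = config$group_log_covariances,
       contaminated = select_contaminated(config))
}

#' Write a cohort to CSV (with optional contamination truth sidecar)
#'
#' Columns `participant_id,group,specimen,il6,tnfa,mpo`; missing
#' concentrations are written as empty strings. The generator truth flag is
#' not part of the main table; pass `truth_path` to write a sidecar CSV
#' `participant_id,contaminated`.
#'
#' @param cohort A `biomarker_cohort` (or compatible data.frame).
#' @param path Output CSV path.
#' @param truth_path Optional path for the per-participant truth sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, truth_path = NULL) {
  main <- cohort[, c("participant_id", "group", "specimen",
                     "il6", "tnfa", "mpo")]
  utils::write.csv(main, path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(truth_path)) {
    if (is.null(cohort$contaminated)) {
      stop("cohort carries no 'contaminated' truth flag to write", call. = FALSE)
    }
    truth <- unique(cohort[, c("participant_id", "contaminated")])
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a cohort case table from CSV
#'
#' Expects (case-insensitively named) columns `participant_id`, `group`,
#' `specimen`, `il6`, `tnfa`, `mpo`; empty cells become missing values.
#'
#' @param path CSV path.
#' @return A `biomarker_cohort` data.frame (without truth flag unless a
#'   `contaminated` column is present).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  names(d) <- tolower(names(d))
  need <- c("participant_id", "group", "specimen", biomarker_names())
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop(sprintf("cohort CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  d$group <- as.integer(d$group)
  if (!all(d$group %in% c(1L, 2L))) {
    stop("group codes must be 1 (patient) or 2 (volunteer)", call. = FALSE)
  }
  for (v in biomarker_names()) d[[v]] <- as.numeric(d[[v]])
  if (anyDuplicated(d[, c("participant_id", "specimen")])) {
    stop("(participant_id, specimen) pairs must be unique within a cohort",
         call. = FALSE)
  }
  class(d) <- c("biomarker_cohort", "data.frame")
  d
}
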