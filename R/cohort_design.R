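#' Adjust blood pressure for antihypertensive treatment
#'
#' Measured BP under treatment underestimates the underlying phenotype;
#' before defining extremes, treated subjects' pressures are shifted by a
#' fixed offset (+10 mmHg systolic, +5 mmHg diastolic), a standard
#' adjustment for treated hypertensives. Untreated subjects are unchanged.
#' The adjustment is tracked in a `bp_adjusted` column and applying it
#' twice is an error.
#'
#' @param cohort data frame with columns `sbp`, `dbp`, `treated` and
#'   optionally `bp_adjusted` (assumed `FALSE` when absent).
#' @param sbp_offset,dbp_offset mmHg added to treated subjects.
#' @return the cohort with adjusted pressures and `bp_adjusted = TRUE`.
#' @export
adjust_bp_for_treatment <- function(cohort, sbp_offset = 10, dbp_offset = 5) {
  stopifnot(is.data.frame(cohort),
            all(c("sbp", "dbp", "treated") %in% names(cohort)))
  if (is.null(cohort$bp_adjusted)) cohort$bp_adjusted <- FALSE
  if (any(cohort$bp_adjusted)) {
    stop_ddcnv("blood pressure already treatment-adjusted; refusing to adjust twice",
               "ddcnv_adjust_error")
  }
  treated <- cohort$treated
  cohort$sbp[treated] <- cohort$sbp[treated] + sbp_offset
  cohort$dbp[treated] <- cohort$dbp[treated] + dbp_offset
  cohort$bp_adjusted <- TRUE
  cohort
}

#' Select extreme SBP groups from a population cohort
#'
#' Takes the lowest `low_decile` and highest `1 - high_decile` fractions
#' of the cohort by (treatment-adjusted) SBP. Membership is by rank under
#' a stable ordering on `(sbp, subject_id)`, so ties are broken
#' deterministically and the two groups are always disjoint; each tail
#' receives `floor(fraction * n)` subjects, the empirical-decile count.
#'
#' @param cohort data frame with `subject_id` and `sbp`.
#' @param low_decile,high_decile quantile cutpoints (defaults 0.1 and 0.9:
#'   bottom and top deciles).
#' @return list with elements `low` and `high` (subset data frames with
#'   `group` set) and `cohort` (the full cohort with `group` set to
#'   `"low"`, `"high"` or `"unselected"`).
#' @export
select_extremes <- function(cohort, low_decile = 0.1, high_decile = 0.9) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "sbp") %in% names(cohort)))
  n <- nrow(cohort)
  if (n < 10L) {
    stop_ddcnv("need at least 10 subjects to take deciles", "ddcnv_input_error")
  }
  stopifnot(is_prob(low_decile), is_prob(high_decile),
            low_decile <= high_decile)
  n_low <- max(1L, floor(n * low_decile + 1e-9))
  n_high <- max(1L, floor(n * (1 - high_decile) + 1e-9))
  if (n_low + n_high > n) {
    stop_ddcnv("tail fractions overlap: fewer subjects than requested extremes",
               "ddcnv_input_error")
  }
  ord <- order(cohort$sbp, cohort$subject_id)
  group <- rep("unselected", n)
  group[ord[seq_len(n_low)]] <- "low"
  group[ord[seq.int(n - n_high + 1L, n)]] <- "high"
  cohort$group <- group
  list(low = cohort[cohort$group == "low", , drop = FALSE],
       high = cohort[cohort$group == "high", , drop = FALSE],
       cohort = cohort)
}

#' Describe an extreme-phenotype cohort design
#'
#' Bundles the population SBP distribution and the realised extreme-group
#' summaries used for the separation and effective-sample-size arithmetic.
#'
#' @param population_mean_sbp,population_sd_sbp population SBP mean and SD
#'   (mmHg).
#' @param n_high,n_low extreme group sizes.
#' @param mean_high,mean_low extreme group SBP means (mmHg).
#' @param sd_high,sd_low extreme group SBP SDs (mmHg), optional.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(population_mean_sbp, population_sd_sbp,
                          n_high, n_low, mean_high, mean_low,
                          sd_high = NA_real_, sd_low = NA_real_) {
  if (!is.finite(population_sd_sbp) || population_sd_sbp <= 0) {
    stop_ddcnv("population SD must be > 0", "ddcnv_input_error")
  }
  stopifnot(is_count(n_high), is_count(n_low))
  structure(
    list(population_mean_sbp = population_mean_sbp,
         population_sd_sbp = population_sd_sbp,
         n_high = as.integer(n_high), n_low = as.integer(n_low),
         mean_high = mean_high, mean_low = mean_low,
         sd_high = sd_high, sd_low = sd_low),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  D <- standardized_separation(x)
  cat(sprintf(
    "Extreme-phenotype design: %d high / %d low subjects\n  group SBP means %.1f / %.1f mmHg; population %.1f (SD %.1f) mmHg\n  separation D = %.2f population SDs; n_eff = %.0f (D^2/4 * N convention)\n",
    x$n_high, x$n_low, x$mean_high, x$mean_low,
    x$population_mean_sbp, x$population_sd_sbp,
    D, effective_sample_size(x)
  ))
  invisible(x)
}

#' Standardized separation of the extreme groups
#'
#' Difference of the two group means in units of the population SD:
#' `D = (mean_high - mean_low) / population_sd`. Invariant to shifting
#' both means by a constant.
#'
#' @param design a [cohort_design()].
#' @return separation in SD units.
#' @export
standardized_separation <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  (design$mean_high - design$mean_low) / design$population_sd_sbp
}

#' Effective random-sample size of an extreme-group comparison
#'
#' Sampling only the tails concentrates phenotypic contrast into few
#' genotyped subjects. The convention used here equates the
#' non-centrality of a two-group extreme comparison with that of an
#' equally sized random sample split at +/- 1 SD around its mean:
#' `n_eff = (D^2 / 4) * (n_high + n_low)`, with `D` the
#' [standardized_separation()]. Under it, two groups 2 SDs apart are
#' exactly equivalent to a random sample of the same total size. Other
#' conventions exist in the power-of-extremes literature (and can give
#' considerably larger equivalents); pass `formula` to use one.
#'
#' @param design a [cohort_design()].
#' @param formula optional `function(D, N)` replacing the default
#'   `D^2/4 * N`.
#' @return equivalent number of randomly sampled subjects.
#' @export
effective_sample_size <- function(design, formula = NULL) {
  D <- standardized_separation(design)
  N <- design$n_high + design$n_low
  if (is.null(formula)) D^2 / 4 * N else formula(D, N)
}
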