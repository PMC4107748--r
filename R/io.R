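# CSV/TSV dialects shared by the pipeline stages.
#
# wells CSV:     sample_id, assay_id, well_id, replicate, n_droplets,
#                k_target, k_reference
# cohort CSV:    subject_id, group, sbp, dbp, age, sex, bmi, treated,
#                true_cn (optional), bp_adjusted (optional)
# estimates TSV: sample_id, assay_id, replicate, channel, lambda, ci_low,
#                ci_high, k, n, wells_pooled, status
# calls TSV:     sample_id, assay_id, cn_hat, ci_low, ci_high,
#                integer_call, status, n_repeats

validate_wells <- function(wells) {
  stopifnot(is.data.frame(wells))
  need <- c("sample_id", "assay_id", "well_id", "replicate", "n_droplets",
            "k_target", "k_reference")
  miss <- setdiff(need, names(wells))
  if (length(miss) > 0L) {
    stop_ddcnv(paste("well table missing columns:", paste(miss, collapse = ", ")),
               "ddcnv_io_error")
  }
  bad <- wells$n_droplets <= 0 |
    wells$k_target < 0 | wells$k_target > wells$n_droplets |
    wells$k_reference < 0 | wells$k_reference > wells$n_droplets
  if (any(bad)) {
    stop_ddcnv(sprintf("%d well(s) violate 0 <= k <= n_droplets, n_droplets > 0",
                       sum(bad)), "ddcnv_io_error")
  }
  wells
}

#' Read and write well-level droplet count tables
#'
#' @param path CSV file in the wells dialect (`sample_id`, `assay_id`,
#'   `well_id`, `replicate`, `n_droplets`, `k_target`, `k_reference`).
#' @return `read_wells`: a validated `droplet_well` data frame.
#' @export
read_wells <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  wells <- validate_wells(wells)
  class(wells) <- c("droplet_well", "data.frame")
  wells
}

#' @rdname read_wells
#' @param wells a `droplet_well` data frame.
#' @export
write_wells <- function(wells, path) {
  utils::write.csv(validate_wells(wells), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cohort phenotype tables
#'
#' @param path CSV file in the cohort dialect (`subject_id`, `group`,
#'   `sbp`, `dbp`, `age`, `sex`, `bmi`, `treated`, optionally `true_cn`
#'   and `bp_adjusted`).
#' @param strict enforce subject invariants (`sbp > dbp > 0`, `age >= 0`,
#'   `bmi > 0`) on read? Default `TRUE` for observed data; simulated
#'   cohorts written by [simulate_cohort()] may rarely violate them by
#'   construction.
#' @return `read_cohort`: a `bp_cohort` data frame.
#' @export
read_cohort <- function(path, strict = TRUE) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sbp", "dbp", "age", "sex", "bmi", "treated")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L) {
    stop_ddcnv(paste("cohort table missing columns:",
                     paste(miss, collapse = ", ")), "ddcnv_io_error")
  }
  cohort$treated <- as.logical(cohort$treated)
  if ("bp_adjusted" %in% names(cohort)) {
    cohort$bp_adjusted <- as.logical(cohort$bp_adjusted)
  }
  if (strict) {
    bad <- !(cohort$sbp > cohort$dbp & cohort$dbp > 0 &
               cohort$age >= 0 & cohort$bmi > 0)
    if (any(bad)) {
      stop_ddcnv(sprintf("%d subject(s) violate phenotype invariants (sbp > dbp > 0, age >= 0, bmi > 0)",
                         sum(bad)), "ddcnv_io_error")
    }
  }
  class(cohort) <- c("bp_cohort", "data.frame")
  cohort
}

#' @rdname read_cohort
#' @param cohort a cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-sample concentration estimate tables
#'
#' @param path TSV file in the estimates dialect.
#' @return `read_estimates`: a `ddpcr_estimates` data frame.
#' @export
read_estimates <- function(path) {
  est <- utils::read.delim(path, stringsAsFactors = FALSE)
  conf <- attr(est, "conf")
  attr(est, "conf") <- if (is.null(conf)) 0.95 else conf
  class(est) <- c("ddpcr_estimates", "data.frame")
  est
}

#' @rdname read_estimates
#' @param estimates a `ddpcr_estimates` data frame.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write copy-number call tables
#'
#' @param path TSV file in the calls dialect.
#' @return `read_calls`: a `cn_calls` data frame.
#' @export
read_calls <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(calls) <- c("cn_calls", "data.frame")
  calls
}

#' @rdname read_calls
#' @param calls a `cn_calls` data frame.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference CNV frequency table
#'
#' @param path TSV with columns `cnv_id`, `loss_freq`, `gain_freq`
#'   (percent) and optionally `source_n`; `NA` marks frequencies the
#'   source does not report. `NULL` loads the shipped reference
#'   comparison table.
#' @return data frame.
#' @export
read_reference_frequencies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dgv_reference.tsv", package = "ddcnv")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}
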