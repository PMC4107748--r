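#' Carrier prevalence as a reporting percentage
#'
#' @param n_carriers,n_genotyped counts with
#'   `0 <= n_carriers <= n_genotyped`, `n_genotyped > 0`.
#' @return percentage rounded to one decimal.
#' @examples
#' prevalence(12, 95)  # 12.6
#' prevalence(2, 92)   # 2.2
#' @export
prevalence <- function(n_carriers, n_genotyped) {
  if (!is_count(n_carriers) || !is_count(n_genotyped) || n_genotyped == 0 ||
      n_carriers > n_genotyped) {
    stop_ddcnv("need 0 <= n_carriers <= n_genotyped with n_genotyped > 0",
               "ddcnv_input_error")
  }
  pct1(n_carriers, n_genotyped)
}

#' Copy-number frequency table by extreme group
#'
#' Joins resolved copy-number calls to the cohort and tabulates counts and
#' within-group percentages per assay x group x integer copy number.
#' Excluded and otherwise non-called samples are dropped from the
#' denominators. Assays with a single copy-number class across all called
#' subjects are flagged monomorphic (no association statistics are
#' meaningful for them).
#'
#' @param calls a `cn_calls` data frame ([call_samples()]).
#' @param cohort a cohort data frame with `subject_id` and `group`.
#' @return data frame of class `cnv_freq_table`: `assay_id`, `group`,
#'   `cn`, `count`, `pct`, `n_group`, plus attribute `monomorphic` (named
#'   logical per assay).
#' @export
build_frequency_table <- function(calls, cohort) {
  stopifnot(is.data.frame(calls), is.data.frame(cohort),
            all(c("subject_id", "group") %in% names(cohort)))
  orphans <- setdiff(calls$sample_id, cohort$subject_id)
  if (length(orphans) > 0L) {
    stop_ddcnv(sprintf("calls for samples absent from the cohort: %s",
                       paste(utils::head(orphans, 5L), collapse = ", ")),
               "ddcnv_input_error")
  }
  called <- calls[calls$status == "called", , drop = FALSE]
  merged <- merge(called, cohort[, c("subject_id", "group")],
                  by.x = "sample_id", by.y = "subject_id")
  rows <- list()
  mono <- logical(0)
  for (assay in sort(unique(calls$assay_id))) {
    sub <- merged[merged$assay_id == assay, , drop = FALSE]
    cns <- sort(unique(sub$integer_call))
    mono[assay] <- length(cns) <= 1L
    for (grp in sort(unique(sub$group))) {
      gsub_ <- sub[sub$group == grp, , drop = FALSE]
      n_grp <- nrow(gsub_)
      for (cn in cns) {
        cnt <- sum(gsub_$integer_call == cn)
        rows[[length(rows) + 1L]] <- data.frame(
          assay_id = assay, group = grp, cn = cn, count = cnt,
          pct = pct1(cnt, n_grp), n_group = n_grp,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "monomorphic") <- mono
  class(out) <- c("cnv_freq_table", "data.frame")
  out
}

#' @export
print.cnv_freq_table <- function(x, ...) {
  cat("Copy-number frequencies by extreme group\n")
  print.data.frame(x)
  mono <- attr(x, "monomorphic")
  if (any(mono)) {
    cat("monomorphic assays (no statistics):",
        paste(names(mono)[mono], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Covariate-adjusted logistic association of extreme group with carriage
#'
#' Fits the binomial GLM `group_high ~ carrier + covariates` by maximum
#' likelihood (iteratively reweighted least squares) and reports the
#' carrier effect on both the coefficient and odds-ratio scales with Wald
#' intervals. Complete separation (a carrier class present in only one
#' group) is detected and reported as a distinct status instead of a
#' silently diverged fit.
#'
#' @param cohort data frame with a `group` column (`"high"` / `"low"`),
#'   the covariates, and the carrier indicator.
#' @param carrier name of the logical/0-1 carrier column.
#' @param covariates character vector of adjustment covariates (default
#'   age, BMI and sex).
#' @param conf confidence level for the Wald interval.
#' @return an object of class `cnv_assoc`: list with `beta`, `se`,
#'   `or`, `ci_low`, `ci_high` (odds-ratio scale), `ci_beta_low`,
#'   `ci_beta_high`, `p_value`, `covariates`, `n_high`, `n_low`,
#'   `status` (`"ok"`, `"separation"`, `"non-convergence"`) and `fit`.
#' @export
logistic_association <- function(cohort, carrier = "carrier",
                                 covariates = c("age", "bmi", "sex"),
                                 conf = 0.95) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort),
            carrier %in% names(cohort),
            all(covariates %in% names(cohort)))
  dat <- cohort[stats::complete.cases(cohort[, c("group", carrier, covariates),
                                             drop = FALSE]), , drop = FALSE]
  dat$.y <- as.integer(dat$group == "high")
  n_high <- sum(dat$.y == 1L)
  n_low <- sum(dat$.y == 0L)
  if (n_high < 2L || n_low < 2L) {
    stop_ddcnv("need at least 2 subjects per group", "ddcnv_input_error")
  }
  for (v in c(carrier, covariates)) {
    if (length(unique(dat[[v]])) < 2L) {
      stop_ddcnv(sprintf("predictor '%s' is constant", v), "ddcnv_input_error")
    }
  }
  form <- stats::as.formula(paste(".y ~", paste(c(carrier, covariates),
                                                collapse = " + ")))
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  # carrier row: first coefficient after the intercept
  idx <- 2L
  beta <- co[idx, "Estimate"]
  se <- co[idx, "Std. Error"]
  status <- if (!fit$converged) {
    "non-convergence"
  } else if (warned_sep || abs(beta) > 15) {
    "separation"
  } else "ok"
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(
    list(beta = beta, se = se, or = exp(beta),
         ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
         ci_beta_low = beta - z * se, ci_beta_high = beta + z * se,
         p_value = p, covariates = covariates,
         n_high = n_high, n_low = n_low, conf = conf,
         status = status, fit = fit),
    class = "cnv_assoc"
  )
}

#' @export
print.cnv_assoc <- function(x, ...) {
  cat(sprintf(
    "Logistic association of extreme-high group with carriage (n = %d high / %d low)\n  adjusted for: %s\n  carrier effect: beta = %.3f (OR = %.3f, %g%% CI %.3f-%.3f), p = %.4g\n  status: %s\n",
    x$n_high, x$n_low, paste(x$covariates, collapse = ", "),
    x$beta, x$or, 100 * x$conf, x$ci_low, x$ci_high, x$p_value, x$status
  ))
  invisible(x)
}

#' Compare observed CNV loss/gain frequencies with reference catalogue values
#'
#' Side-by-side comparison of observed loss and gain percentages against
#' user-supplied reference (e.g. DGV-reported) frequencies, with absolute
#' differences. Descriptive only; no test is performed.
#'
#' @param observed data frame with `cnv_id`, `loss_pct`, `gain_pct`.
#' @param reference data frame with `cnv_id`, `loss_freq`, `gain_freq`
#'   (percent) and optionally `source_n`; see
#'   `system.file("extdata", "dgv_reference.tsv", package = "ddcnv")` for
#'   the dialect.
#' @return data frame with observed and reference percentages and
#'   `loss_diff` / `gain_diff` (observed minus reference).
#' @export
compare_reference_frequencies <- function(observed, reference) {
  stopifnot(is.data.frame(observed),
            all(c("cnv_id", "loss_pct", "gain_pct") %in% names(observed)),
            is.data.frame(reference),
            all(c("cnv_id", "loss_freq", "gain_freq") %in% names(reference)))
  missing_ids <- setdiff(observed$cnv_id, reference$cnv_id)
  if (length(missing_ids) > 0L) {
    stop_ddcnv(sprintf("no reference frequencies for: %s",
                       paste(missing_ids, collapse = ", ")),
               "ddcnv_input_error")
  }
  m <- merge(observed, reference, by = "cnv_id")
  m$loss_diff <- m$loss_pct - m$loss_freq
  m$gain_diff <- m$gain_pct - m$gain_freq
  m[order(m$cnv_id), , drop = FALSE]
}

#' Observed loss/gain frequencies per assay or CNV
#'
#' Fraction of called samples below (loss) and above (gain) two copies,
#' per assay; optionally expanded to one row per CNV via a region table
#' mapping CNV ids to assays.
#'
#' @param calls a `cn_calls` data frame.
#' @param regions optional list of `genomic_region` objects; when given,
#'   rows are emitted per CNV id (several CNVs can share one assay).
#' @return data frame with `cnv_id` (or `assay_id`), `loss_pct`,
#'   `gain_pct`, `n_called`.
#' @export
loss_gain_frequencies <- function(calls, regions = NULL) {
  called <- calls[calls$status == "called", , drop = FALSE]
  per_assay <- do.call(rbind, lapply(split(called, called$assay_id), function(g) {
    data.frame(assay_id = g$assay_id[1L],
               loss_pct = pct1(sum(g$integer_call < 2L), nrow(g)),
               gain_pct = pct1(sum(g$integer_call > 2L), nrow(g)),
               n_called = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(per_assay) <- NULL
  if (is.null(regions)) return(per_assay)
  rows <- lapply(regions, function(r) {
    hit <- per_assay[per_assay$assay_id == r$assay_id, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    data.frame(cnv_id = r$cnv_id, hit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
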