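#' Copies per diploid genome from duplexed target and reference estimates
#'
#' The reference assay targets a locus carried at two copies per diploid
#' genome (RNaseP), so the copy number of the target locus is
#' \eqn{\hat{c} = 2\,\hat\lambda_t / \hat\lambda_r}. The interval is
#' propagated by the delta method on \eqn{\log(\lambda_t/\lambda_r)}:
#' the squared relative standard errors of the two channels are summed,
#' and the bound back-transformed around the ratio. The ratio is scale
#' invariant: multiplying both concentrations by a constant leaves it
#' unchanged.
#'
#' @param target,reference `lambda_estimate` objects for the two channels
#'   of the same sample.
#' @param conf confidence level.
#' @return list with `cn_hat`, `ci_low`, `ci_high`.
#' @details A zero or saturated reference channel leaves the ratio
#'   undefined and raises an error of class `ddcnv_reference_error`.
#'   A zero target channel (no amplification on a valid reference) returns
#'   `cn_hat = 0` with an upper bound propagated from the channel bounds.
#' @export
cn_ratio <- function(target, reference, conf = 0.95) {
  stopifnot(inherits(target, "lambda_estimate"),
            inherits(reference, "lambda_estimate"))
  if (!is.finite(reference$lambda) || reference$lambda <= 0) {
    stop_ddcnv("reference channel has no signal: copy number undefined",
               "ddcnv_reference_error")
  }
  cn <- 2 * target$lambda / reference$lambda
  if (target$lambda <= 0) {
    # degenerate target: bound from interval arithmetic on the channel CIs
    ci_low <- 0
    ci_high <- 2 * target$ci_high / reference$ci_low
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    s <- sqrt(rel_se(target)^2 + rel_se(reference)^2)
    ci_low <- cn * exp(-z * s)
    ci_high <- cn * exp(z * s)
  }
  list(cn_hat = cn, ci_low = ci_low, ci_high = ci_high)
}

# relative standard error of lambda-hat, from the pooled droplet counts
rel_se <- function(est) {
  p <- est$k / est$n
  sqrt(p / (est$n * (1 - p))) / est$lambda
}

new_cn_call <- function(sample_id, assay_id, cn_hat, ci_low, ci_high,
                        integer_call, status, n_repeats = 1L) {
  structure(
    list(sample_id = sample_id, assay_id = assay_id,
         cn_hat = cn_hat, ci_low = ci_low, ci_high = ci_high,
         integer_call = integer_call, status = status,
         n_repeats = as.integer(n_repeats)),
    class = "cn_call"
  )
}

#' @export
print.cn_call <- function(x, ...) {
  lab <- if (is.na(x$integer_call)) x$status else
    sprintf("%d copies (%s)", x$integer_call, x$status)
  cat(sprintf("CN call %s / %s: %s  [cn = %.3f, CI %.3f-%.3f, %d attempt%s]\n",
              x$sample_id, x$assay_id, lab, x$cn_hat, x$ci_low, x$ci_high,
              x$n_repeats, if (x$n_repeats == 1L) "" else "s"))
  invisible(x)
}

#' Call integer copy number from an estimate and its confidence interval
#'
#' A sample is called at integer copy number m when m is the only integer
#' in the calling universe (1..`max_cn`, default 3) contained in the 95%
#' interval of the measured copy number. If no candidate integer lies in
#' the interval the status is `"no_integer"`; if two or more do, the
#' measurement is `"ambiguous"`. Non-called samples are repeated and, if
#' still unresolved, excluded (see [resolve_sample()]).
#'
#' @param cn_hat estimated copies per diploid genome.
#' @param ci_low,ci_high interval bounds (`ci_low <= ci_high`).
#' @param max_cn largest integer in the calling universe (default 3).
#' @param sample_id,assay_id identifiers carried into the call object.
#' @return a `cn_call` object.
#' @export
call_integer <- function(cn_hat, ci_low, ci_high, max_cn = 3L,
                         sample_id = NA_character_, assay_id = NA_character_) {
  stopifnot(is.numeric(cn_hat), is.numeric(ci_low), is.numeric(ci_high),
            is_count(max_cn), max_cn >= 1)
  if (ci_low > ci_high) {
    stop_ddcnv("inverted confidence interval", "ddcnv_input_error")
  }
  candidates <- seq_len(max_cn)
  inside <- candidates[candidates >= ci_low & candidates <= ci_high]
  if (length(inside) == 1L) {
    new_cn_call(sample_id, assay_id, cn_hat, ci_low, ci_high,
                as.integer(inside), "called")
  } else if (length(inside) == 0L) {
    new_cn_call(sample_id, assay_id, cn_hat, ci_low, ci_high,
                NA_integer_, "no_integer")
  } else {
    new_cn_call(sample_id, assay_id, cn_hat, ci_low, ci_high,
                NA_integer_, "ambiguous")
  }
}

#' Resolve repeated calls for one sample into a final genotype
#'
#' Repeated measurements of a sample must agree: if at least one attempt
#' yielded an integer call and all called attempts are concordant, that
#' call stands (with `n_repeats` recording the attempts). Discordant
#' integer calls, or two or more attempts none of which resolved to an
#' integer, exclude the sample. A single unresolved attempt is returned
#' as-is (the sample still awaits its repeat).
#'
#' @param calls list of `cn_call` objects for one sample and assay.
#' @return a single `cn_call`.
#' @export
resolve_sample <- function(calls) {
  if (inherits(calls, "cn_call")) calls <- list(calls)
  if (length(calls) == 0L) stop_ddcnv("no calls to resolve", "ddcnv_input_error")
  stopifnot(all(vapply(calls, inherits, logical(1), "cn_call")))
  n <- length(calls)
  statuses <- vapply(calls, `[[`, character(1), "status")
  called <- calls[statuses == "called"]
  out <- if (length(called) > 0L) {
    ints <- vapply(called, `[[`, integer(1), "integer_call")
    if (length(unique(ints)) == 1L) {
      first <- called[[1L]]
      first
    } else {
      first <- calls[[1L]]
      new_cn_call(first$sample_id, first$assay_id, first$cn_hat,
                  first$ci_low, first$ci_high, NA_integer_, "excluded")
    }
  } else if (n >= 2L) {
    first <- calls[[1L]]
    new_cn_call(first$sample_id, first$assay_id, first$cn_hat,
                first$ci_low, first$ci_high, NA_integer_, "excluded")
  } else {
    calls[[1L]]
  }
  out$n_repeats <- n
  out
}

#' Exclusion rate as a reporting percentage
#'
#' @param n_excluded,n_total counts, `0 <= n_excluded <= n_total`,
#'   `n_total > 0`.
#' @return percentage rounded to one decimal.
#' @examples
#' exclusion_rate(14, 188)  # 7.4
#' @export
exclusion_rate <- function(n_excluded, n_total) {
  if (!is_count(n_excluded) || !is_count(n_total) || n_total == 0 ||
      n_excluded > n_total) {
    stop_ddcnv("need 0 <= n_excluded <= n_total with n_total > 0",
               "ddcnv_input_error")
  }
  pct1(n_excluded, n_total)
}

# build a minimal lambda_estimate from an estimates-table row
row_estimate <- function(row, conf) {
  structure(
    list(lambda = row$lambda, ci_low = row$ci_low, ci_high = row$ci_high,
         k = row$k, n = row$n, wells_pooled = row$wells_pooled,
         conf = conf, method = "delta"),
    class = "lambda_estimate"
  )
}

# per-replicate call from one target row and one reference row
call_one <- function(trow, rrow, max_cn, conf) {
  sid <- trow$sample_id; aid <- trow$assay_id
  if (trow$status == "saturated") {
    return(new_cn_call(sid, aid, NA_real_, NA_real_, NA_real_,
                       NA_integer_, "saturated"))
  }
  if (rrow$status == "saturated" || rrow$k == 0) {
    return(new_cn_call(sid, aid, NA_real_, NA_real_, NA_real_,
                       NA_integer_, "failed_amplification"))
  }
  ratio <- cn_ratio(row_estimate(trow, conf), row_estimate(rrow, conf),
                    conf = conf)
  call_integer(ratio$cn_hat, ratio$ci_low, ratio$ci_high, max_cn = max_cn,
               sample_id = sid, assay_id = aid)
}

#' Call copy number for every sample in an estimates table
#'
#' Pairs the target and reference channel of each sample (and replicate),
#' forms the reference-normalised copy number, applies the CI-containment
#' integer calling rule, and resolves repeated attempts per sample by
#' concordance. Saturated target channels and failed (zero or saturated)
#' reference channels are carried through as their own statuses.
#'
#' @param estimates a `ddpcr_estimates` data frame from [quantify_wells()].
#' @param max_cn largest integer in the calling universe.
#' @return a data frame of class `cn_calls`, one row per sample x assay:
#'   `sample_id`, `assay_id`, `cn_hat`, `ci_low`, `ci_high`,
#'   `integer_call`, `status`, `n_repeats`. The per-replicate calls are
#'   attached as attribute `"replicate_calls"`.
#' @export
call_samples <- function(estimates, max_cn = 3L) {
  stopifnot(is.data.frame(estimates))
  conf <- attr(estimates, "conf")
  if (is.null(conf)) conf <- 0.95
  keys <- paste(estimates$sample_id, estimates$assay_id, estimates$replicate,
                sep = "\r")
  rep_calls <- lapply(split(estimates, keys), function(g) {
    trow <- g[g$channel == "target", , drop = FALSE]
    rrow <- g[g$channel == "reference", , drop = FALSE]
    if (nrow(trow) != 1L || nrow(rrow) != 1L) {
      stop_ddcnv("each sample/replicate needs exactly one target and one reference row",
                 "ddcnv_input_error")
    }
    call_one(as.list(trow), as.list(rrow), max_cn, conf)
  })
  sample_keys <- vapply(rep_calls, function(cl) {
    paste(cl$sample_id, cl$assay_id, sep = "\r")
  }, character(1))
  resolved <- lapply(split(rep_calls, sample_keys), resolve_sample)
  as_row <- function(cl) {
    data.frame(sample_id = cl$sample_id, assay_id = cl$assay_id,
               cn_hat = cl$cn_hat, ci_low = cl$ci_low, ci_high = cl$ci_high,
               integer_call = cl$integer_call, status = cl$status,
               n_repeats = cl$n_repeats, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(resolved, as_row))
  rownames(out) <- NULL
  out <- out[order(out$assay_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  reps <- do.call(rbind, lapply(rep_calls, as_row))
  rownames(reps) <- NULL
  attr(out, "replicate_calls") <- reps
  class(out) <- c("cn_calls", "data.frame")
  out
}
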