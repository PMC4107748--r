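#' Estimate template concentration per droplet from droplet counts
#'
#' In digital PCR the template molecules partition into droplets
#' approximately Poisson, so the fraction of positive droplets \eqn{p = k/n}
#' determines the mean copies per droplet as \eqn{\lambda = -\ln(1 - p)}.
#' The 95% interval uses the delta-method normal approximation on
#' \eqn{\lambda} (standard error \eqn{\sqrt{p / (n(1-p))}}) in the bulk
#' regime, and an exact Clopper-Pearson binomial interval on \eqn{p},
#' transformed through \eqn{-\ln(1-p)}, when either droplet class has fewer
#' than 5 droplets (where the normal approximation is unreliable).
#'
#' @param k number of positive droplets (0 <= k < n).
#' @param n total number of accepted droplets (> 0).
#' @param conf confidence level for the interval (default 0.95).
#'
#' @return An object of class `lambda_estimate`: a list with elements
#'   `lambda`, `ci_low`, `ci_high`, `k`, `n`, `wells_pooled`, `conf` and
#'   `method` (`"delta"` or `"clopper-pearson"`).
#'
#' @details A saturated well (`k == n`) has no finite estimate (the
#'   estimator diverges) and raises an error of class
#'   `ddcnv_saturated_error` rather than returning a number.
#'
#' @examples
#' estimate_lambda(5000, 14000)   # lambda = log(14/9) ~ 0.4418
#' estimate_lambda(0, 10000)      # empty well: lambda 0, CI lower bound 0
#' @export
estimate_lambda <- function(k, n, conf = 0.95) {
  if (!is_count(n) || n <= 0 || !is_count(k) || k > n) {
    stop_ddcnv("malformed droplet counts: need 0 <= k <= n, n > 0",
               "ddcnv_input_error")
  }
  stopifnot(is_prob(conf), conf > 0, conf < 1)
  if (k == n) {
    stop_ddcnv(sprintf("saturated well (k = n = %d): no finite estimate", n),
               "ddcnv_saturated_error")
  }
  p <- k / n
  lambda <- -log1p(-p)
  alpha <- 1 - conf
  if (k < 5 || (n - k) < 5) {
    p_lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    p_hi <- stats::qbeta(1 - alpha / 2, k + 1, n - k)
    ci_low <- -log1p(-p_lo)
    ci_high <- -log1p(-p_hi)
    method <- "clopper-pearson"
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    se <- sqrt(p / (n * (1 - p)))
    ci_low <- max(0, lambda - z * se)
    ci_high <- lambda + z * se
    method <- "delta"
  }
  structure(
    list(lambda = lambda, ci_low = ci_low, ci_high = ci_high,
         k = as.integer(k), n = as.integer(n), wells_pooled = 1L,
         conf = conf, method = method),
    class = "lambda_estimate"
  )
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat(sprintf(
    "ddPCR concentration estimate: lambda = %.5f copies/droplet\n  %g%% CI [%.5f, %.5f]  (k = %d / n = %d droplets, %d well%s, %s interval)\n",
    x$lambda, 100 * x$conf, x$ci_low, x$ci_high, x$k, x$n,
    x$wells_pooled, if (x$wells_pooled == 1L) "" else "s", x$method
  ))
  invisible(x)
}

#' Merge replicate wells of one sample and assay
#'
#' Pools droplet counts across wells at the droplet level (sums of `k` and
#' `n`) before estimating, the maximum-likelihood "merged well" estimator
#' under the Poisson partition model; per-well averaging of lambdas is not
#' performed. Two identical wells therefore give the same lambda as one,
#' with a narrower interval.
#'
#' @param wells a `droplet_well` data frame (see [simulate_well()] /
#'   [read_wells()]) with rows from a single sample and assay.
#' @param conf confidence level.
#' @return list with `lambda_estimate` elements `target` and `reference`,
#'   each with `wells_pooled` set to the number of wells merged.
#' @export
merge_replicates <- function(wells, conf = 0.95) {
  wells <- validate_wells(wells)
  if (nrow(wells) == 0L) stop_ddcnv("no wells to merge", "ddcnv_input_error")
  if (length(unique(wells$sample_id)) != 1L ||
      length(unique(wells$assay_id)) != 1L) {
    stop_ddcnv("merge_replicates requires wells from a single sample and assay",
               "ddcnv_input_error")
  }
  n <- sum(wells$n_droplets)
  out <- list(
    target = estimate_lambda(sum(wells$k_target), n, conf = conf),
    reference = estimate_lambda(sum(wells$k_reference), n, conf = conf)
  )
  out$target$wells_pooled <- nrow(wells)
  out$reference$wells_pooled <- nrow(wells)
  out
}

#' Copies per reaction from a concentration estimate
#'
#' Scales mean copies per droplet by the number of droplets in the reaction;
#' the confidence bounds scale identically.
#'
#' @param est a `lambda_estimate`.
#' @param n_droplets droplets in the reaction.
#' @return list with `copies`, `ci_low`, `ci_high`.
#' @export
copies_per_reaction <- function(est, n_droplets) {
  stopifnot(inherits(est, "lambda_estimate"))
  if (!is_count(n_droplets) || n_droplets <= 0) {
    stop_ddcnv("n_droplets must be a positive count", "ddcnv_input_error")
  }
  list(copies = est$lambda * n_droplets,
       ci_low = est$ci_low * n_droplets,
       ci_high = est$ci_high * n_droplets)
}

#' DNA mass needed for a target number of haploid genome copies
#'
#' One haploid human genome weighs about 3.3 pg, and accurate ddPCR copy
#' number work wants roughly 10,000 genome copies per reaction, i.e. 33 ng.
#'
#' @param target_copies haploid genome copies wanted in the reaction.
#' @param mass_per_haploid_pg mass of one haploid genome, picograms
#'   (default 3.3).
#' @return required mass in nanograms.
#' @examples
#' dna_mass_for_copies(10000)  # 33 ng
#' @export
dna_mass_for_copies <- function(target_copies, mass_per_haploid_pg = 3.3) {
  stopifnot(is.numeric(target_copies), length(target_copies) == 1L,
            is.numeric(mass_per_haploid_pg), length(mass_per_haploid_pg) == 1L)
  if (target_copies < 0 || mass_per_haploid_pg < 0) {
    stop_ddcnv("copies and mass per haploid genome must be nonnegative",
               "ddcnv_input_error")
  }
  target_copies * mass_per_haploid_pg / 1000  # pg -> ng
}

#' Quantify a table of wells into per-group concentration estimates
#'
#' Groups wells by sample and assay (and replicate, unless `merge_replicates
#' = TRUE`, which pools every replicate of a sample into one merged-well
#' estimate), pools droplet counts within each group, and estimates lambda
#' for both duplex channels. Saturated groups are reported with status
#' `"saturated"` and no numeric estimate.
#'
#' @param wells a `droplet_well` data frame.
#' @param merge_replicates pool all replicates of a sample before
#'   estimating? Default `FALSE` (one estimate per replicate, so repeat
#'   concordance can be assessed downstream).
#' @param conf confidence level.
#' @return a data frame of class `ddpcr_estimates` with one row per
#'   group x channel: `sample_id`, `assay_id`, `replicate`, `channel`,
#'   `lambda`, `ci_low`, `ci_high`, `k`, `n`, `wells_pooled`, `status`.
#' @export
quantify_wells <- function(wells, merge_replicates = FALSE, conf = 0.95) {
  wells <- validate_wells(wells)
  if (nrow(wells) == 0L) stop_ddcnv("no wells supplied", "ddcnv_input_error")
  keys <- if (merge_replicates) {
    paste(wells$sample_id, wells$assay_id, sep = "\r")
  } else {
    paste(wells$sample_id, wells$assay_id, wells$replicate, sep = "\r")
  }
  groups <- split(wells, keys)
  rows <- lapply(groups, function(g) {
    n <- sum(g$n_droplets)
    rep_id <- if (merge_replicates) NA_integer_ else g$replicate[1L]
    one <- function(channel, k) {
      est <- tryCatch(estimate_lambda(k, n, conf = conf),
                      ddcnv_saturated_error = function(e) NULL)
      data.frame(
        sample_id = g$sample_id[1L], assay_id = g$assay_id[1L],
        replicate = rep_id, channel = channel,
        lambda = if (is.null(est)) NA_real_ else est$lambda,
        ci_low = if (is.null(est)) NA_real_ else est$ci_low,
        ci_high = if (is.null(est)) NA_real_ else est$ci_high,
        k = as.integer(k), n = as.integer(n),
        wells_pooled = nrow(g),
        status = if (is.null(est)) "saturated" else "ok",
        stringsAsFactors = FALSE
      )
    }
    rbind(one("target", sum(g$k_target)),
          one("reference", sum(g$k_reference)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "conf") <- conf
  class(out) <- c("ddpcr_estimates", "data.frame")
  out
}
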