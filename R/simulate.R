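#' Configuration for a simulated duplex ddPCR well
#'
#' Describes one well of a duplexed copy-number assay: a reference channel
#' at mean occupancy `lambda_reference` copies per droplet, and a target
#' channel whose occupancy is tied to the simulated genotype as
#' `(true_cn / 2) * lambda_reference` (a two-copy sample runs at the
#' reference concentration). The target concentration is always derived,
#' never stored independently.
#'
#' Defaults reflect a typical run of the assays modelled here: about
#' 14,000 accepted droplets per well and lambda chosen so a reaction holds
#' roughly 5,000-8,000 template copies (lambda about 0.4-0.6); false
#' positive/negative rates default to 0 and exist as stress-test knobs
#' only.
#'
#' @param n_droplets accepted droplets in the well.
#' @param lambda_reference mean reference copies per droplet (> 0).
#' @param true_cn simulated integer copies per diploid genome (>= 0).
#' @param false_positive_rate,false_negative_rate per-droplet, per-channel
#'   misclassification probabilities in `[0, 1)`.
#' @param seed integer seed, or `NULL` to use the ambient RNG stream.
#' @return a `well_sim_config` list.
#' @export
well_sim_config <- function(n_droplets = 14000L, lambda_reference = 0.5,
                            true_cn = 2L, false_positive_rate = 0,
                            false_negative_rate = 0, seed = NULL) {
  if (!is_count(n_droplets) || n_droplets <= 0) {
    stop_ddcnv("n_droplets must be a positive count", "ddcnv_input_error")
  }
  if (!is.numeric(lambda_reference) || length(lambda_reference) != 1L ||
      !is.finite(lambda_reference) || lambda_reference <= 0) {
    stop_ddcnv("lambda_reference must be > 0", "ddcnv_input_error")
  }
  if (!is_count(true_cn)) {
    stop_ddcnv("true_cn must be a nonnegative integer", "ddcnv_input_error")
  }
  for (r in c(false_positive_rate, false_negative_rate)) {
    if (!is_prob(r) || r >= 1) {
      stop_ddcnv("false call rates must lie in [0, 1)", "ddcnv_input_error")
    }
  }
  structure(
    list(n_droplets = as.integer(n_droplets),
         lambda_reference = lambda_reference,
         true_cn = as.integer(true_cn),
         false_positive_rate = false_positive_rate,
         false_negative_rate = false_negative_rate,
         seed = seed),
    class = "well_sim_config"
  )
}

# per-droplet probability of reading positive: Poisson occupancy >= 1,
# thinned by false negatives, with false positives firing on droplets that
# would otherwise read negative
p_positive <- function(lambda, fp, fn) {
  q <- -expm1(-lambda) * (1 - fn)
  q + fp * (1 - q)
}

#' Simulate one duplex ddPCR well
#'
#' Droplet occupancy in each channel is Poisson with the channel's mean
#' (reference `lambda_reference`, target `(true_cn/2) * lambda_reference`);
#' a droplet reads positive when it is occupied and not a false negative,
#' or when a false positive fires. Channels are read independently, as the
#' copy-number estimator assumes. Per-droplet indicators are iid
#' Bernoulli, so the positive counts are drawn directly from the exact
#' Binomial distribution they imply.
#'
#' @param config a [well_sim_config()].
#' @param sample_id,assay_id,well_id,replicate identifiers stamped on the
#'   returned row.
#' @return one-row `droplet_well` data frame: `sample_id`, `assay_id`,
#'   `well_id`, `replicate`, `n_droplets`, `k_target`, `k_reference`.
#' @examples
#' simulate_well(well_sim_config(seed = 1))
#' @export
simulate_well <- function(config, sample_id = "S1", assay_id = "A1",
                          well_id = "W1", replicate = 1L) {
  stopifnot(inherits(config, "well_sim_config"))
  lambda_target <- (config$true_cn / 2) * config$lambda_reference
  p_t <- p_positive(lambda_target, config$false_positive_rate,
                    config$false_negative_rate)
  p_r <- p_positive(config$lambda_reference, config$false_positive_rate,
                    config$false_negative_rate)
  counts <- with_seed(config$seed, {
    c(stats::rbinom(1L, config$n_droplets, p_t),
      stats::rbinom(1L, config$n_droplets, p_r))
  })
  out <- data.frame(
    sample_id = sample_id, assay_id = assay_id, well_id = well_id,
    replicate = as.integer(replicate), n_droplets = config$n_droplets,
    k_target = counts[1L], k_reference = counts[2L],
    stringsAsFactors = FALSE
  )
  class(out) <- c("droplet_well", "data.frame")
  out
}

#' Simulate a plate of wells with replicates
#'
#' One well per sample x replicate. Each well's seed is derived
#' deterministically from the master seed and a stable hash of its
#' (sample, replicate) label, so any subset of the plate reproduces
#' identically without seed bookkeeping.
#'
#' @param configs a single [well_sim_config()] shared by all samples, or a
#'   named list with one config per sample (names become sample ids).
#' @param sample_ids sample identifiers; defaults to `names(configs)` or
#'   `S1..Sn`.
#' @param replicates wells per sample (>= 1).
#' @param assay_id assay identifier stamped on every well.
#' @param master_seed integer master seed for the plate.
#' @return a `droplet_well` data frame with one row per well.
#' @export
simulate_plate <- function(configs, sample_ids = NULL, replicates = 1L,
                           assay_id = "A1", master_seed = 1L) {
  if (inherits(configs, "well_sim_config")) {
    if (is.null(sample_ids)) sample_ids <- "S1"
    configs <- rep(list(configs), length(sample_ids))
  } else {
    stopifnot(is.list(configs), length(configs) >= 1L)
    if (is.null(sample_ids)) {
      sample_ids <- if (!is.null(names(configs))) names(configs) else
        sprintf("S%d", seq_along(configs))
    }
    stopifnot(length(sample_ids) == length(configs))
  }
  if (!is_count(replicates) || replicates < 1) {
    stop_ddcnv("replicates must be >= 1", "ddcnv_input_error")
  }
  rows <- vector("list", length(configs) * replicates)
  i <- 0L
  for (s in seq_along(configs)) {
    for (r in seq_len(replicates)) {
      cfg <- configs[[s]]
      cfg$seed <- derive_seed(master_seed, sample_ids[s], r)
      i <- i + 1L
      rows[[i]] <- simulate_well(
        cfg, sample_id = sample_ids[s], assay_id = assay_id,
        well_id = sprintf("%s_%s_r%d", assay_id, sample_ids[s], r),
        replicate = r
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("droplet_well", "data.frame")
  out
}

#' Configuration for a simulated extreme blood-pressure cohort
#'
#' Two-group extreme-phenotype design: subjects sampled from the highest
#' and lowest SBP deciles of a population cohort. Phenotypes are Gaussian
#' within group; sex is Bernoulli; antihypertensive treatment occurs only
#' in the high group; the deletion genotype (1 vs 2 copies of the target
#' CNV) is Bernoulli with a group-specific prevalence. Defaults are the
#' characteristics of the extreme cohort this package models: 96 high /
#' 92 low subjects, SBP 165.9 +/- 12.3 vs 98.6 +/- 5.2 mmHg, DBP
#' 94.4 +/- 10.8 vs 64.3 +/- 7.2 mmHg, age 55.1 +/- 8.3 vs 32.6 +/- 14.5
#' years, BMI 28.3 +/- 4.5 vs 22.7 +/- 3.2 kg/m^2, about half male,
#' 53.1% of the high group on treatment, and deletion prevalence 12.6% vs
#' 2.2%.
#'
#' Blood pressures are on the treatment-adjusted scale (the scale on which
#' extremes are defined), so simulated cohorts carry `bp_adjusted = TRUE`.
#'
#' @param n_high,n_low group sizes.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd,age_mean,age_sd,bmi_mean,bmi_sd
#'   named numeric vectors with elements `high` and `low` (mmHg, years,
#'   kg/m^2).
#' @param frac_male probability a subject is male.
#' @param frac_treated_high probability a high-group subject is on
#'   antihypertensive treatment.
#' @param deletion_prevalence named vector (`high`, `low`) of carrier
#'   probabilities for the one-copy deletion genotype.
#' @param seed integer seed or `NULL`.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(
    n_high = 96L, n_low = 92L,
    sbp_mean = c(high = 165.9, low = 98.6), sbp_sd = c(high = 12.3, low = 5.2),
    dbp_mean = c(high = 94.4, low = 64.3), dbp_sd = c(high = 10.8, low = 7.2),
    age_mean = c(high = 55.1, low = 32.6), age_sd = c(high = 8.3, low = 14.5),
    bmi_mean = c(high = 28.3, low = 22.7), bmi_sd = c(high = 4.5, low = 3.2),
    frac_male = 0.5, frac_treated_high = 0.531,
    deletion_prevalence = c(high = 0.126, low = 0.022),
    seed = NULL) {
  if (!is_count(n_high) || !is_count(n_low)) {
    stop_ddcnv("group sizes must be nonnegative counts", "ddcnv_input_error")
  }
  for (sd in c(sbp_sd, dbp_sd, age_sd, bmi_sd)) {
    if (!is.finite(sd) || sd <= 0) {
      stop_ddcnv("all SDs must be > 0", "ddcnv_input_error")
    }
  }
  for (f in c(frac_male, frac_treated_high, deletion_prevalence)) {
    if (!is_prob(f)) {
      stop_ddcnv("fractions and prevalences must lie in [0, 1]",
                 "ddcnv_input_error")
    }
  }
  grp <- function(x) {
    stopifnot(all(c("high", "low") %in% names(x)))
    x[c("high", "low")]
  }
  structure(
    list(n_high = as.integer(n_high), n_low = as.integer(n_low),
         sbp_mean = grp(sbp_mean), sbp_sd = grp(sbp_sd),
         dbp_mean = grp(dbp_mean), dbp_sd = grp(dbp_sd),
         age_mean = grp(age_mean), age_sd = grp(age_sd),
         bmi_mean = grp(bmi_mean), bmi_sd = grp(bmi_sd),
         frac_male = frac_male, frac_treated_high = frac_treated_high,
         deletion_prevalence = grp(deletion_prevalence),
         seed = seed),
    class = "cohort_sim_config"
  )
}

#' Simulate an extreme blood-pressure cohort
#'
#' Draws subjects per group with Gaussian phenotypes, Bernoulli sex,
#' Bernoulli treatment (high group only) and a Bernoulli deletion genotype
#' at the group prevalence; `true_cn` is 1 for carriers and 2 otherwise.
#' Phenotypes are drawn from the configured Gaussians without truncation
#' so configured moments are recovered exactly in expectation; physical
#' range checks (`sbp > dbp > 0`, `age >= 0`, ...) belong to ingestion of
#' observed data, not to the generator.
#'
#' @param config a [cohort_sim_config()].
#' @return a `bp_cohort` data frame: `subject_id`, `group`, `sbp`, `dbp`,
#'   `age`, `sex`, `bmi`, `treated`, `true_cn`, `bp_adjusted`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  draw_group <- function(group, n, prefix) {
    if (n == 0L) {
      return(data.frame(subject_id = character(0), group = character(0),
                        sbp = numeric(0), dbp = numeric(0), age = numeric(0),
                        sex = character(0), bmi = numeric(0),
                        treated = logical(0), true_cn = integer(0),
                        bp_adjusted = logical(0), stringsAsFactors = FALSE))
    }
    data.frame(
      subject_id = sprintf("%s%03d", prefix, seq_len(n)),
      group = group,
      sbp = stats::rnorm(n, config$sbp_mean[[group]], config$sbp_sd[[group]]),
      dbp = stats::rnorm(n, config$dbp_mean[[group]], config$dbp_sd[[group]]),
      age = stats::rnorm(n, config$age_mean[[group]], config$age_sd[[group]]),
      sex = ifelse(stats::rbinom(n, 1L, config$frac_male) == 1L,
                   "male", "female"),
      bmi = stats::rnorm(n, config$bmi_mean[[group]], config$bmi_sd[[group]]),
      treated = if (group == "high") {
        stats::rbinom(n, 1L, config$frac_treated_high) == 1L
      } else rep(FALSE, n),
      true_cn = 2L - stats::rbinom(n, 1L, config$deletion_prevalence[[group]]),
      bp_adjusted = TRUE,
      stringsAsFactors = FALSE
    )
  }
  out <- with_seed(config$seed, {
    rbind(draw_group("high", config$n_high, "H"),
          draw_group("low", config$n_low, "L"))
  })
  rownames(out) <- NULL
  class(out) <- c("bp_cohort", "data.frame")
  out
}
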