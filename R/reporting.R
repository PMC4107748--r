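#' Per-assay run summary in dMIQE style
#'
#' Accounts for every sample exactly once per assay: droplet statistics
#' (mean and standard error of the mean droplets per well), genotyped vs
#' excluded samples with the one-decimal exclusion percentage, the
#' fraction of samples measured more than once, and replicate concordance
#' (fraction of repeated samples whose attempts all yielded the same
#' integer call).
#'
#' @param wells a `droplet_well` data frame.
#' @param calls resolved calls from [call_samples()] (per-replicate calls
#'   are taken from its `"replicate_calls"` attribute when present).
#' @return data frame of class `run_summary`, one row per assay:
#'   `assay_id`, `n_wells`, `mean_droplets`, `sem_droplets`,
#'   `n_samples`, `n_genotyped`, `n_excluded`, `pct_excluded`,
#'   `replicate_fraction`, `concordance`.
#' @export
summarize_run <- function(wells, calls) {
  wells <- validate_wells(wells)
  stopifnot(is.data.frame(calls))
  reps <- attr(calls, "replicate_calls")
  rows <- lapply(sort(unique(wells$assay_id)), function(assay) {
    w <- wells[wells$assay_id == assay, , drop = FALSE]
    cl <- calls[calls$assay_id == assay, , drop = FALSE]
    n_wells <- nrow(w)
    sem <- if (n_wells > 1L) stats::sd(w$n_droplets) / sqrt(n_wells) else 0
    n_samples <- nrow(cl)
    n_genotyped <- sum(cl$status == "called")
    n_excluded <- n_samples - n_genotyped
    pct_excl <- if (n_samples > 0L) exclusion_rate(n_excluded, n_samples) else NA_real_
    # replicate accounting from wells; concordance from per-replicate calls
    wells_per_sample <- table(w$sample_id)
    repeated <- names(wells_per_sample)[wells_per_sample > 1L]
    rep_frac <- if (n_samples > 0L) length(repeated) / n_samples else NA_real_
    concord <- NA_real_
    if (!is.null(reps) && length(repeated) > 0L) {
      r <- reps[reps$assay_id == assay & reps$sample_id %in% repeated, ,
                drop = FALSE]
      per_sample <- split(r$integer_call, r$sample_id)
      agree <- vapply(per_sample, function(ints) {
        length(ints) > 1L && !anyNA(ints) && length(unique(ints)) == 1L
      }, logical(1))
      concord <- mean(agree)
    }
    data.frame(assay_id = assay, n_wells = n_wells,
               mean_droplets = mean(w$n_droplets), sem_droplets = sem,
               n_samples = n_samples, n_genotyped = n_genotyped,
               n_excluded = n_excluded, pct_excluded = pct_excl,
               replicate_fraction = rep_frac, concordance = concord,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("run_summary", "data.frame")
  out
}

#' @export
print.run_summary <- function(x, ...) {
  cat("ddPCR run summary (per assay)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Default pipeline configuration
#'
#' Nested list consumed by [run_pipeline()]. Simulation defaults are the
#' study conditions the package models (see [cohort_sim_config()] and
#' [well_sim_config()]); `repeat_fraction` is the fraction of samples
#' measured in two independent wells (within the 29-67% range typical of
#' confirmatory repeats).
#'
#' @param seed master seed for every stochastic stage.
#' @param assay_id assay label for the simulated deletion assay.
#' @param n_droplets,lambda_reference,false_positive_rate,false_negative_rate
#'   well simulation parameters.
#' @param repeat_fraction fraction of samples run in duplicate.
#' @param max_cn calling universe upper bound.
#' @param conf confidence level used throughout.
#' @param covariates logistic adjustment covariates.
#' @param cohort a [cohort_sim_config()] (its seed is derived from
#'   `seed`), or a path to a cohort CSV to use instead of simulating.
#' @param wells optional path to a wells CSV to use instead of simulating.
#' @param reference_frequencies optional path to a reference frequency
#'   TSV for the descriptive catalogue comparison.
#' @return config list.
#' @export
pipeline_config <- function(seed = 1L, assay_id = "Hs01327571",
                            n_droplets = 14000L, lambda_reference = 0.5,
                            false_positive_rate = 0, false_negative_rate = 0,
                            repeat_fraction = 0.4, max_cn = 3L, conf = 0.95,
                            covariates = c("age", "bmi", "sex"),
                            cohort = cohort_sim_config(),
                            wells = NULL, reference_frequencies = NULL) {
  list(seed = as.integer(seed), assay_id = assay_id,
       n_droplets = n_droplets, lambda_reference = lambda_reference,
       false_positive_rate = false_positive_rate,
       false_negative_rate = false_negative_rate,
       repeat_fraction = repeat_fraction, max_cn = max_cn, conf = conf,
       covariates = covariates, cohort = cohort, wells = wells,
       reference_frequencies = reference_frequencies)
}

read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_ddcnv("reading YAML configs requires the 'yaml' package",
               "ddcnv_io_error")
  }
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config,
                 raw[setdiff(names(raw), "cohort")])
  if (!is.null(raw$cohort)) {
    cfg$cohort <- if (is.character(raw$cohort)) raw$cohort else
      do.call(cohort_sim_config, raw$cohort)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> quantify -> call -> associate -> report, fully
#' deterministic under the config's master seed. Each stage logs counts in
#' and out; all artifacts are written under `out_dir`: `cohort.csv`,
#' `wells.csv`, `estimates.tsv`, `calls.tsv`, `report.json` and
#' `summary.txt`.
#'
#' @param config a [pipeline_config()] list, or a path to a YAML file with
#'   the same keys.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage logging.
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `wells`, `estimates`, `calls`, `freq_table`, `association`,
#'   `wilcoxon`, `run_summary`, `report`) and `paths` to the artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ddcnv_run_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- cohort ---------------------------------------------------------------
  cohort <- stage("cohort", {
    if (is.character(config$cohort)) {
      read_cohort(config$cohort, strict = FALSE)
    } else {
      cc <- config$cohort
      cc$seed <- derive_seed(config$seed, "cohort", 0L)
      simulate_cohort(cc)
    }
  })
  say("cohort: %d subjects (%d high / %d low)", nrow(cohort),
      sum(cohort$group == "high"), sum(cohort$group == "low"))

  # -- wells ----------------------------------------------------------------
  wells <- stage("wells", {
    if (!is.null(config$wells)) {
      read_wells(config$wells)
    } else {
      repeated <- with_seed(derive_seed(config$seed, "repeats", 0L), {
        stats::runif(nrow(cohort)) < config$repeat_fraction
      })
      rows <- lapply(seq_len(nrow(cohort)), function(i) {
        cfg <- well_sim_config(
          n_droplets = config$n_droplets,
          lambda_reference = config$lambda_reference,
          true_cn = cohort$true_cn[i],
          false_positive_rate = config$false_positive_rate,
          false_negative_rate = config$false_negative_rate
        )
        simulate_plate(cfg, sample_ids = cohort$subject_id[i],
                       replicates = if (repeated[i]) 2L else 1L,
                       assay_id = config$assay_id,
                       master_seed = config$seed)
      })
      out <- do.call(rbind, rows)
      class(out) <- c("droplet_well", "data.frame")
      out
    }
  })
  say("wells: %d wells across %d samples", nrow(wells),
      length(unique(wells$sample_id)))

  # -- quantify & call ------------------------------------------------------
  estimates <- stage("quantify", quantify_wells(wells, conf = config$conf))
  say("quantify: %d channel estimates", nrow(estimates))
  calls <- stage("call", call_samples(estimates, max_cn = config$max_cn))
  say("call: %d samples, %d called, %d not called", nrow(calls),
      sum(calls$status == "called"), sum(calls$status != "called"))

  # -- association ----------------------------------------------------------
  freq_table <- stage("associate", build_frequency_table(calls, cohort))
  mono <- attr(freq_table, "monomorphic")
  assoc <- NULL
  n_tests <- 0L
  wilcox <- list()
  merged <- merge(calls[calls$status == "called", , drop = FALSE],
                  cohort, by.x = "sample_id", by.y = "subject_id")
  merged$carrier <- merged$integer_call < 2L
  if (!isTRUE(mono[[config$assay_id]]) &&
      length(unique(merged$carrier)) == 2L) {
    assoc <- stage("associate",
                   logistic_association(merged, carrier = "carrier",
                                        covariates = config$covariates,
                                        conf = config$conf))
    n_tests <- n_tests + 1L
    for (grp in c("high", "low")) {
      g <- merged[merged$group == grp, , drop = FALSE]
      for (pheno in c("sbp", "dbp")) {
        x <- g[[pheno]][g$carrier]
        y <- g[[pheno]][!g$carrier]
        if (length(x) >= 2L && length(y) >= 2L) {
          wilcox[[paste(grp, pheno, sep = "_")]] <-
            wilcoxon_rank_sum(x, y)
          n_tests <- n_tests + 1L
        }
      }
    }
  } else {
    say("associate: assay monomorphic or single carrier class; statistics skipped")
  }

  # -- catalogue comparison -------------------------------------------------
  ref_cmp <- NULL
  if (!is.null(config$reference_frequencies)) {
    ref <- read_reference_frequencies(config$reference_frequencies)
    obs <- loss_gain_frequencies(calls)
    obs <- data.frame(cnv_id = obs$assay_id, obs[-1L], stringsAsFactors = FALSE)
    ref_cmp <- tryCatch(compare_reference_frequencies(obs, ref),
                        error = function(e) NULL)
  }

  # -- report ---------------------------------------------------------------
  rsum <- stage("report", summarize_run(wells, calls))
  report <- list(
    seed = config$seed,
    samples = list(total = nrow(calls),
                   genotyped = sum(calls$status == "called"),
                   excluded = sum(calls$status != "called")),
    frequency_table = as.data.frame(freq_table),
    monomorphic_assays = names(mono)[mono],
    association = if (!is.null(assoc)) {
      assoc[c("beta", "se", "or", "ci_low", "ci_high", "p_value",
              "covariates", "n_high", "n_low", "status")]
    },
    wilcoxon = lapply(wilcox, function(w) w[c("statistic", "p_value", "method")]),
    reference_comparison = ref_cmp,
    run_summary = as.data.frame(rsum),
    n_tests_run = n_tests
  )

  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    wells = file.path(out_dir, "wells.csv"),
    estimates = file.path(out_dir, "estimates.tsv"),
    calls = file.path(out_dir, "calls.tsv"),
    report = file.path(out_dir, "report.json"),
    summary = file.path(out_dir, "summary.txt")
  )
  write_cohort(cohort, paths$cohort)
  write_wells(wells, paths$wells)
  write_estimates(estimates, paths$estimates)
  write_calls(calls, paths$calls)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(c(
    "ddcnv pipeline summary",
    sprintf("seed: %d", config$seed),
    sprintf("samples: %d (%d genotyped, %d excluded)",
            report$samples$total, report$samples$genotyped,
            report$samples$excluded),
    if (!is.null(assoc)) sprintf(
      "carrier association: beta = %.3f, OR = %.3f (%g%% CI %.3f-%.3f), p = %.4g [%s]",
      assoc$beta, assoc$or, 100 * assoc$conf, assoc$ci_low, assoc$ci_high,
      assoc$p_value, assoc$status) else "carrier association: not testable",
    sprintf("tests run (unadjusted): %d", n_tests)
  ), paths$summary)
  say("report: written to %s", out_dir)

  invisible(list(cohort = cohort, wells = wells, estimates = estimates,
                 calls = calls, freq_table = freq_table, association = assoc,
                 wilcoxon = wilcox, run_summary = rsum, report = report,
                 paths = paths))
}
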