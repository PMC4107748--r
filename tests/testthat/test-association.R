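test_that("prevalence reporting matches one-decimal convention", {
  expect_equal(prevalence(12, 95), 12.6)
  expect_equal(prevalence(2, 92), 2.2)
  expect_equal(prevalence(0, 92), 0)
  expect_error(prevalence(1, 0), class = "ddcnv_input_error")
  expect_error(prevalence(5, 4), class = "ddcnv_input_error")
})

# build a calls + cohort pair realising given per-group CN counts
fixture_calls <- function(counts, assay = "A1") {
  # counts: list(high = c(`1` = ..., `2` = ...), low = ...)
  rows <- list(); subs <- list(); i <- 0L
  for (grp in names(counts)) {
    for (cn in names(counts[[grp]])) {
      for (j in seq_len(counts[[grp]][[cn]])) {
        i <- i + 1L
        id <- sprintf("%s%04d", toupper(substr(grp, 1, 1)), i)
        rows[[i]] <- data.frame(sample_id = id, assay_id = assay,
                                cn_hat = as.numeric(cn),
                                ci_low = as.numeric(cn) - 0.1,
                                ci_high = as.numeric(cn) + 0.1,
                                integer_call = as.integer(cn),
                                status = "called", n_repeats = 1L)
        subs[[i]] <- data.frame(subject_id = id, group = grp)
      }
    }
  }
  list(calls = structure(do.call(rbind, rows),
                         class = c("cn_calls", "data.frame")),
       cohort = do.call(rbind, subs))
}

test_that("frequency tables reproduce per-group counts and percentages", {
  fx <- fixture_calls(list(high = c(`1` = 12, `2` = 83),
                           low = c(`1` = 2, `2` = 90)))
  ft <- build_frequency_table(fx$calls, fx$cohort)
  get <- function(grp, cn) ft[ft$group == grp & ft$cn == cn, ]
  expect_equal(get("high", 1)$count, 12)
  expect_equal(get("high", 1)$pct, 12.6)
  expect_equal(get("high", 2)$pct, 87.4)
  expect_equal(get("low", 1)$pct, 2.2)
  expect_equal(get("low", 2)$pct, 97.8)
  # percentages sum to 100 within rounding per group
  for (grp in c("high", "low")) {
    expect_lt(abs(sum(ft$pct[ft$group == grp]) - 100), 0.2)
  }
  expect_false(attr(ft, "monomorphic")[["A1"]])
})

test_that("monomorphic assays are flagged and orphan samples rejected", {
  fx <- fixture_calls(list(high = c(`2` = 20), low = c(`2` = 20)))
  ft <- build_frequency_table(fx$calls, fx$cohort)
  expect_true(attr(ft, "monomorphic")[["A1"]])
  expect_equal(ft$pct, c(100, 100))

  expect_error(build_frequency_table(fx$calls, fx$cohort[-1, ]),
               class = "ddcnv_input_error")
})

test_that("overall variation fraction matches pooled-group arithmetic", {
  fx <- fixture_calls(list(high = c(`2` = 74, `3` = 16),
                           low = c(`2` = 63, `3` = 19)))
  lg <- loss_gain_frequencies(fx$calls)
  expect_equal(lg$gain_pct, prevalence(35, 172))
  expect_equal(lg$gain_pct, 20.3)
  expect_equal(lg$loss_pct, 0)
})

test_that("logistic MLE reproduces the analytic 2x2 odds ratio", {
  dat <- expand_2x2(12, 83, 2, 90)
  fit <- logistic_association(dat, carrier = "carrier",
                              covariates = character(0))
  expect_equal(fit$or, cross_product_or(12, 83, 2, 90), tolerance = 1e-7)
  expect_identical(fit$status, "ok")
  expect_lt(fit$p_value, 0.05)
  # CI brackets the estimate on both scales
  expect_lt(fit$ci_low, fit$or); expect_gt(fit$ci_high, fit$or)
  expect_equal(fit$beta, log(fit$or), tolerance = 1e-12)
})

test_that("null and separated genotype patterns are reported as such", {
  null_dat <- expand_2x2(10, 80, 10, 80)
  fit0 <- logistic_association(null_dat, carrier = "carrier",
                               covariates = character(0))
  expect_equal(fit0$or, 1, tolerance = 1e-7)
  expect_gt(fit0$p_value, 0.99)

  sep_dat <- expand_2x2(12, 80, 0, 90)
  fit_sep <- logistic_association(sep_dat, carrier = "carrier",
                                  covariates = character(0))
  expect_identical(fit_sep$status, "separation")

  const <- expand_2x2(0, 90, 0, 92)
  expect_error(logistic_association(const, carrier = "carrier",
                                    covariates = character(0)),
               class = "ddcnv_input_error")
})

test_that("covariate-adjusted fit uses all requested covariates", {
  set.seed(5)
  dat <- expand_2x2(12, 83, 2, 90)
  dat$age <- rnorm(nrow(dat), ifelse(dat$group == "high", 55, 33), 9)
  dat$bmi <- rnorm(nrow(dat), ifelse(dat$group == "high", 28, 23), 4)
  dat$sex <- sample(c("male", "female"), nrow(dat), replace = TRUE)
  fit <- logistic_association(dat)
  expect_identical(fit$covariates, c("age", "bmi", "sex"))
  expect_equal(length(coef(fit$fit)), 5L)  # intercept + carrier + 3 covariates
  expect_true(is.finite(fit$p_value))
})

test_that("reference frequency comparison is descriptive with exact differences", {
  obs <- data.frame(cnv_id = c("esv27061", "dgv1306e1"),
                    loss_pct = c(7.4, 0), gain_pct = c(0, 20.3))
  ref <- read_reference_frequencies()
  cmp <- compare_reference_frequencies(obs, ref)
  expect_equal(cmp$gain_diff[cmp$cnv_id == "esv27061"], -5.8)
  expect_equal(cmp$gain_diff[cmp$cnv_id == "dgv1306e1"], 20.3)

  same <- data.frame(cnv_id = "dgv1306e1", loss_pct = 0, gain_pct = 0)
  expect_equal(compare_reference_frequencies(same, ref)$gain_diff, 0)

  missing <- data.frame(cnv_id = "nsv999", loss_pct = 1, gain_pct = 1)
  expect_error(compare_reference_frequencies(missing, ref),
               class = "ddcnv_input_error")
})
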