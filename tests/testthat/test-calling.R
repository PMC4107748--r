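est <- function(k, n) estimate_lambda(k, n)

test_that("copy-number ratio identities hold", {
  e <- est(5000, 14000)
  r <- cn_ratio(e, e)
  expect_equal(r$cn_hat, 2)
  expect_lt(r$ci_low, 2)
  expect_gt(r$ci_high, 2)

  # hemizygous deletion: lambda_t = lambda_r / 2
  half <- est(2711, 14000)  # -ln(1-p) ~ lambda/2 region; exactness via direct ratio
  r1 <- cn_ratio(structure(modifyList(e, list(lambda = e$lambda / 2)),
                           class = "lambda_estimate"), e)
  expect_equal(r1$cn_hat, 1)

  # closed-form ratio 2 * 0.33 / 0.44
  a <- structure(modifyList(e, list(lambda = 0.33)), class = "lambda_estimate")
  b <- structure(modifyList(e, list(lambda = 0.44)), class = "lambda_estimate")
  expect_equal(cn_ratio(a, b)$cn_hat, 1.5, tolerance = 1e-12)
})

test_that("copy-number ratio is scale invariant", {
  e1 <- est(3000, 14000)
  e2 <- est(5000, 14000)
  base <- cn_ratio(e1, e2)$cn_hat
  for (c_mult in c(0.5, 3, 10)) {
    s1 <- structure(modifyList(e1, list(lambda = e1$lambda * c_mult)),
                    class = "lambda_estimate")
    s2 <- structure(modifyList(e2, list(lambda = e2$lambda * c_mult)),
                    class = "lambda_estimate")
    expect_equal(cn_ratio(s1, s2)$cn_hat, base, tolerance = 1e-12)
  }
})

test_that("zero or missing reference signals reference failure", {
  e <- est(5000, 14000)
  zero <- structure(modifyList(e, list(lambda = 0)), class = "lambda_estimate")
  expect_error(cn_ratio(e, zero), class = "ddcnv_reference_error")
})

test_that("integer calling implements the CI containment rule", {
  # oracle: enumerate the integers inside the interval
  cases <- list(
    list(cn = 1.05, lo = 0.91, hi = 1.19, status = "called", call = 1L),
    list(cn = 1.5, lo = 1.2, hi = 1.8, status = "no_integer", call = NA_integer_),
    list(cn = 1.6, lo = 0.9, hi = 2.1, status = "ambiguous", call = NA_integer_),
    list(cn = 2.0, lo = 1.99, hi = 2.01, status = "called", call = 2L),
    list(cn = 3.4, lo = 3.2, hi = 3.9, status = "no_integer", call = NA_integer_),
    list(cn = 0.4, lo = 0.2, hi = 0.8, status = "no_integer", call = NA_integer_)
  )
  for (cs in cases) {
    got <- call_integer(cs$cn, cs$lo, cs$hi)
    expect_identical(got$status, cs$status)
    expect_identical(got$integer_call, cs$call)
    inside <- enum_integers_in(cs$lo, cs$hi)
    if (length(inside) == 1L) expect_identical(got$integer_call, as.integer(inside))
  }
  expect_error(call_integer(2, 2.5, 1.5), class = "ddcnv_input_error")
})

test_that("calling is deterministic and total over random intervals", {
  set.seed(21)
  for (i in 1:200) {
    cn <- runif(1, 0, 5)
    half <- runif(1, 0.01, 1.5)
    got <- call_integer(cn, cn - half, cn + half)
    inside <- enum_integers_in(cn - half, cn + half)
    want <- if (length(inside) == 1L) "called" else if (length(inside) == 0L)
      "no_integer" else "ambiguous"
    expect_identical(got$status, want)
    expect_identical(got$status,
                     call_integer(cn, cn - half, cn + half)$status)
  }
})

test_that("copy numbers above the calling universe are not called", {
  got <- call_integer(4.0, 3.8, 4.2, max_cn = 3L)
  expect_identical(got$status, "no_integer")
  got5 <- call_integer(4.0, 3.8, 4.2, max_cn = 5L)
  expect_identical(got5$integer_call, 4L)
})

test_that("repeat resolution requires concordance and excludes the unresolved", {
  cc <- function(status, int = NA_integer_) {
    call_integer(if (is.na(int)) 1.5 else int,
                 if (is.na(int)) 1.2 else int - 0.1,
                 if (is.na(int)) 1.8 else int + 0.1)
  }
  c1 <- cc("called", 1L); c2 <- cc("called", 2L); nf <- cc("no_integer")

  r <- resolve_sample(list(c1, c1))
  expect_identical(r$status, "called")
  expect_identical(r$integer_call, 1L)
  expect_identical(r$n_repeats, 2L)

  expect_identical(resolve_sample(list(nf, nf))$status, "excluded")
  expect_identical(resolve_sample(list(c1, c2))$status, "excluded")
  # a single unresolved attempt awaits its repeat
  expect_identical(resolve_sample(list(nf))$status, "no_integer")
  expect_error(resolve_sample(list()), class = "ddcnv_input_error")
})

test_that("exclusion percentages use one-decimal reporting", {
  expect_equal(exclusion_rate(14, 188), 7.4)
  expect_equal(exclusion_rate(7, 188), 3.7)
  expect_equal(exclusion_rate(0, 188), 0)
  expect_error(exclusion_rate(1, 0), class = "ddcnv_input_error")
  expect_error(exclusion_rate(5, 4), class = "ddcnv_input_error")
})

test_that("simulated duplex wells are called to the true copy number", {
  # moderate size here; acceptance runs the full grid
  acc <- list()
  for (cn in c(1L, 2L, 3L)) {
    calls <- simulate_and_call(cn, lambda_ref = 0.5, n_droplets = 14000,
                               n_wells = 60, master_seed = 100 + cn)
    called <- calls[calls$status == "called", ]
    expect_gt(nrow(called) / nrow(calls), 0.85)
    expect_true(all(called$integer_call == cn))
  }
})

test_that("non-called fraction under CN 2 tracks CI non-coverage", {
  # regression bound: with a calibrated 95% interval the per-well call rate
  # sits near 95%; far outside that signals a broken interval
  calls <- simulate_and_call(2L, lambda_ref = 0.5, n_droplets = 14000,
                             n_wells = 300, master_seed = 77)
  rate <- mean(calls$status == "called")
  expect_gt(rate, 0.90)
  expect_lt(rate, 0.99)
})

test_that("call_samples carries saturated and failed channels as statuses", {
  wells <- data.frame(
    sample_id = c("ok", "sat", "ref0"), assay_id = "A1",
    well_id = c("w1", "w2", "w3"), replicate = 1L,
    n_droplets = 14000L,
    k_target = c(5000L, 14000L, 5000L),
    k_reference = c(5000L, 5000L, 0L)
  )
  class(wells) <- c("droplet_well", "data.frame")
  calls <- call_samples(quantify_wells(wells))
  expect_identical(calls$status[calls$sample_id == "sat"], "saturated")
  expect_identical(calls$status[calls$sample_id == "ref0"],
                   "failed_amplification")
  expect_identical(calls$status[calls$sample_id == "ok"], "called")
  expect_identical(calls$integer_call[calls$sample_id == "ok"], 2L)
})
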