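test_that("zero template with zero false positives never yields positives", {
  cfg <- well_sim_config(n_droplets = 5000, lambda_reference = 0.5,
                         true_cn = 0, seed = 3)
  for (s in 1:5) {
    cfg$seed <- s
    expect_identical(simulate_well(cfg)$k_target, 0L)
  }
})

test_that("positive fraction converges to the Poisson zero-class probability", {
  # 200 wells at lambda = 0.5: mean positive fraction within 4 MC SEs of
  # 1 - exp(-0.5)
  n <- 14000L
  lambda <- 0.5
  cfg <- well_sim_config(n_droplets = n, lambda_reference = lambda)
  wells <- simulate_plate(cfg, sample_ids = sprintf("s%03d", 1:200),
                          master_seed = 91)
  p_hat <- mean(wells$k_reference / wells$n_droplets)
  p_true <- 1 - exp(-lambda)
  se <- sqrt(p_true * (1 - p_true) / (n * 200))
  expect_lt(abs(p_hat - p_true), 4 * se)
})

test_that("false call rates shift the positive fraction as modelled", {
  fp <- 0.01; fn <- 0.05; lambda <- 0.5; n <- 14000L
  cfg <- well_sim_config(n_droplets = n, lambda_reference = lambda,
                         false_positive_rate = fp, false_negative_rate = fn)
  wells <- simulate_plate(cfg, sample_ids = sprintf("s%03d", 1:200),
                          master_seed = 17)
  q <- (1 - exp(-lambda)) * (1 - fn)
  p_true <- q + fp * (1 - q)
  p_hat <- mean(wells$k_reference / wells$n_droplets)
  se <- sqrt(p_true * (1 - p_true) / (n * 200))
  expect_lt(abs(p_hat - p_true), 4 * se)
})

test_that("well simulation is deterministic under a fixed seed", {
  cfg <- well_sim_config(seed = 123)
  expect_identical(simulate_well(cfg), simulate_well(cfg))
  p1 <- simulate_plate(well_sim_config(), sample_ids = c("a", "b"),
                       replicates = 2L, master_seed = 5)
  p2 <- simulate_plate(well_sim_config(), sample_ids = c("a", "b"),
                       replicates = 2L, master_seed = 5)
  expect_identical(p1, p2)
})

test_that("plates have one well per sample x replicate with distinct draws", {
  plate <- simulate_plate(well_sim_config(), sample_ids = "s1",
                          replicates = 2L, master_seed = 1)
  expect_equal(nrow(plate), 2L)
  expect_identical(unique(plate$sample_id), "s1")
  expect_false(identical(plate$k_target[1], plate$k_target[2]) &&
                 identical(plate$k_reference[1], plate$k_reference[2]))

  plate96 <- simulate_plate(well_sim_config(),
                            sample_ids = sprintf("s%02d", 1:96),
                            replicates = 1L, master_seed = 1)
  expect_equal(nrow(plate96), 96L)
  expect_error(simulate_plate(well_sim_config(), replicates = 0),
               class = "ddcnv_input_error")
})

test_that("invalid well configs are rejected", {
  expect_error(well_sim_config(n_droplets = 0), class = "ddcnv_input_error")
  expect_error(well_sim_config(lambda_reference = 0), class = "ddcnv_input_error")
  expect_error(well_sim_config(false_positive_rate = 1), class = "ddcnv_input_error")
  expect_error(well_sim_config(true_cn = -1), class = "ddcnv_input_error")
})

test_that("cohort simulator recovers configured group moments and prevalences", {
  reps <- 25L
  cfg <- cohort_sim_config()
  sims <- lapply(seq_len(reps), function(i) {
    cfg$seed <- 1000L + i
    simulate_cohort(cfg)
  })
  all_sub <- do.call(rbind, sims)
  high <- all_sub[all_sub$group == "high", ]
  low <- all_sub[all_sub$group == "low", ]

  # means within 3 SE of the configured values
  tol_mean <- function(sd, n) 3 * sd / sqrt(n)
  expect_lt(abs(mean(high$sbp) - 165.9), tol_mean(12.3, nrow(high)))
  expect_lt(abs(mean(low$sbp) - 98.6), tol_mean(5.2, nrow(low)))
  expect_lt(abs(mean(high$age) - 55.1), tol_mean(8.3, nrow(high)))
  expect_lt(abs(mean(low$bmi) - 22.7), tol_mean(3.2, nrow(low)))
  # SDs in the right ballpark
  expect_equal(sd(high$sbp), 12.3, tolerance = 0.1)
  expect_equal(sd(low$sbp), 5.2, tolerance = 0.1)

  # binomial recovery of prevalences and fractions (3 SE)
  tol_p <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  del_high <- mean(high$true_cn == 1L)
  del_low <- mean(low$true_cn == 1L)
  expect_lt(abs(del_high - 0.126), tol_p(0.126, nrow(high)))
  expect_lt(abs(del_low - 0.022), tol_p(0.022, nrow(low)))
  expect_lt(abs(mean(high$treated) - 0.531), tol_p(0.531, nrow(high)))
  expect_false(any(low$treated))
})

test_that("cohort simulation handles empty groups and rejects bad configs", {
  cfg <- cohort_sim_config(n_high = 0L, n_low = 10L, seed = 1)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$group == "high"), 0L)
  expect_equal(sum(sim$group == "low"), 10L)

  expect_error(cohort_sim_config(frac_male = 1.2), class = "ddcnv_input_error")
  expect_error(cohort_sim_config(sbp_sd = c(high = 0, low = 5)),
               class = "ddcnv_input_error")

  cfg2 <- cohort_sim_config(seed = 9)
  expect_identical(simulate_cohort(cfg2), simulate_cohort(cfg2))
})
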