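# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# solve 1 - exp(-lambda) = k/n for lambda by bisection
bisect_lambda <- function(k, n, tol = 1e-14) {
  p <- k / n
  if (p == 0) return(0)
  lo <- 0
  hi <- 1
  while (1 - exp(-hi) < p) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (1 - exp(-mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exhaustive two-sided rank-sum p over all C(n+m, n) labelings
enum_ranksum_p <- function(x, y) {
  m <- length(x)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(m)])
  sums <- utils::combn(ranks, m, sum)
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# integers of 1..max_cn inside a closed interval (oracle for call_integer)
enum_integers_in <- function(lo, hi, max_cn = 3) {
  ints <- seq_len(max_cn)
  ints[ints >= lo & ints <= hi]
}

# 2x2 cross-product odds ratio
cross_product_or <- function(a, b, c, d) (a * d) / (b * c)

# expand a 2x2 carrier-by-group table into subject-level rows
expand_2x2 <- function(carrier_high, noncarrier_high, carrier_low,
                      noncarrier_low) {
  data.frame(
    group = rep(c("high", "high", "low", "low"),
                c(carrier_high, noncarrier_high, carrier_low, noncarrier_low)),
    carrier = rep(c(TRUE, FALSE, TRUE, FALSE),
                  c(carrier_high, noncarrier_high, carrier_low, noncarrier_low))
  )
}

# simulate duplex wells at a known copy number and call them; returns the
# resolved per-well calls (one replicate each)
simulate_and_call <- function(true_cn, lambda_ref, n_droplets, n_wells,
                              master_seed, max_cn = 3L) {
  cfg <- well_sim_config(n_droplets = n_droplets,
                         lambda_reference = lambda_ref, true_cn = true_cn)
  wells <- simulate_plate(cfg,
                          sample_ids = sprintf("cn%d_s%04d", true_cn,
                                               seq_len(n_wells)),
                          replicates = 1L, master_seed = master_seed)
  call_samples(quantify_wells(wells), max_cn = max_cn)
}
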