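ahp_proto <- function() standard_protocols()$ahp_burst50hz

# smooth constructed AHP trace: holding -69, trough exactly -75 mV at
# +80 ms, value exactly -72 mV at +1 s (the generator's closed form is not
# used; this is an independent construction)
constructed_ahp_sweep <- function(fs = 10000) {
  proto <- ahp_proto()
  off <- stim_offset(proto)       # 0.55 s
  dur <- 3
  t <- (seq_len(fs * dur) - 1) / fs
  rel <- t - off
  m <- -6; s <- -3; t_m <- 0.08; tau_r <- 0.01
  tau_d <- (1 - t_m) / log(m / s)
  v <- rep(-69, length(t))
  early <- rel > 0 & rel <= t_m
  late <- rel > t_m
  v[early] <- -69 + m * (1 - exp(-rel[early] / tau_r)) /
    (1 - exp(-t_m / tau_r))
  v[late] <- -69 + m * exp(-(rel[late] - t_m) / tau_d)
  pf_sweep(v, fs, proto)
}

test_that("mAHP/sAHP are measured relative to holding on constructed traces", {
  m <- measure_ahp(constructed_ahp_sweep())
  expect_equal(m$mAHP, -6, tolerance = 0.05)
  expect_equal(m$sAHP, -3, tolerance = 0.05)

  flat <- pf_sweep(rep(-69, 3 * 10000), 10000, ahp_proto())
  mf <- measure_ahp(flat)
  expect_equal(mf$mAHP, 0)
  expect_equal(mf$sAHP, 0)

  short <- pf_sweep(rep(-69, 10000), 10000, ahp_proto())  # 1 s sweep
  expect_error(measure_ahp(short), class = "pf_out_of_range")
})

test_that("per-cell AHP uses the sweep-averaged trace and recovers truth", {
  g <- generate_ephys_cohort(
    group_spec("YN", n_cells = 30, mahp_mean = -5.6, mahp_sd = 0.8,
               sahp_mean = -3.6, sahp_sd = 0.9),
    seed = 81, protocols = character(0), include_adp = FALSE,
    sample_rate = 2000)
  vals <- t(vapply(g$cohort$cells, function(cl) {
    a <- ahp_cell(cl)
    expect_equal(a$n_sweeps, 5)
    c(a$mAHP, a$sAHP)
  }, numeric(2)))
  truth <- g$truth$cells
  se_m <- sd(truth$mahp) / sqrt(nrow(truth))
  se_s <- sd(truth$sahp) / sqrt(nrow(truth))
  expect_lt(abs(mean(vals[, 1]) - mean(truth$mahp)), 3 * se_m + 0.05)
  expect_lt(abs(mean(vals[, 2]) - mean(truth$sahp)), 3 * se_s + 0.05)
  # per-cell agreement, not just group means
  expect_lt(max(abs(vals[, 1] - truth$mahp)), 0.3)
  expect_lt(max(abs(vals[, 2] - truth$sahp)), 0.3)
})

adp_proto <- function() standard_protocols()$adp_250ms_10mv

test_that("ADP peak and AUC follow the rectangle/flat analytic cases", {
  fs <- 10000
  proto <- adp_proto()
  off <- stim_offset(proto)       # 2.0 s
  dur <- 6
  t <- (seq_len(fs * dur) - 1) / fs
  v <- ifelse(t > off & t <= off + 1, -52 + 2, -52)
  sw <- pf_sweep(v, fs, proto)
  m <- measure_adp(sw, holding = -52, window_end = off + 2)
  expect_equal(m$adp_peak, 2, tolerance = 0.01)
  expect_equal(m$auc, 2 * 1000, tolerance = 2)   # 2 mV x 1000 ms

  flat <- pf_sweep(rep(-52, fs * dur), fs, proto)
  mf <- measure_adp(flat, holding = -52)
  expect_equal(mf$adp_peak, 0)
  expect_equal(mf$auc, 0)
})

test_that("AUC is additive over windows and linear in a voltage offset", {
  g <- tiny_cohort(seed = 82, n_cells = 1)
  sw <- g$cohort$cells[[1]]$sweeps$adp_250ms_10mv[[1]]
  off <- stim_offset(sw$protocol)
  hold <- estimate_holding(sw)
  a_full <- measure_adp(sw, holding = hold, check_spikes = FALSE)$auc
  a1 <- measure_adp(sw, holding = hold, window_end = off + 1,
                    check_spikes = FALSE)$auc
  # additivity: integral over (off, end] = (off, off+1] + (off+1, end]
  sw2 <- sw
  a2_manual <- a_full - a1
  t <- sweep_time(sw)
  sel <- t > off + 1 & t <= sw$duration
  dv <- sw$voltage[sel] - hold
  a2_direct <- sum((dv[-1] + dv[-length(dv)]) / 2) * 1000 / sw$sample_rate
  expect_equal(a2_manual, a2_direct, tolerance = 1)

  # auc(V + c) = auc(V) + c * window (c = 1 mV)
  swc <- sw
  swc$voltage <- sw$voltage + 1
  ac <- measure_adp(swc, holding = hold, check_spikes = FALSE)$auc
  window_ms <- (sw$duration - off) * 1000
  expect_equal(ac, a_full + window_ms, tolerance = 1.5)

  # peak >= mean depolarization over a window containing the peak
  m <- measure_adp(sw, holding = hold, check_spikes = FALSE,
                   window_end = off + 2)
  expect_gte(m$adp_peak + 0.05, m$auc / 2000)
})

test_that("post-offset spikes raise the contamination error", {
  fs <- 10000
  proto <- adp_proto()
  v <- build_trace_with_aps(3.0, fs = fs, duration = 6, base = -52)
  sw <- pf_sweep(v, fs, proto)
  expect_error(measure_adp(sw, holding = -52),
               class = "pf_spike_contamination")
})

test_that("generator ADP peaks are recovered per cell", {
  g <- generate_ephys_cohort(
    group_spec("YN", n_cells = 15, adp_peak_mean = 2.5, adp_peak_sd = 0.8),
    seed = 83, protocols = character(0), include_ahp = FALSE,
    sample_rate = 2000, adp_sweep_duration = 6)
  got <- vapply(g$cohort$cells, function(cl) adp_cell(cl)$adp_peak,
                numeric(1))
  expect_lt(max(abs(got - g$truth$cells$adp_peak)), 0.25)
})

test_that("ADP-firing relationships recover correlations and the boundary", {
  # perfectly linear pair
  x <- c(1, 2, 3, 4, 5)
  r <- adp_firing_relationships(x, mean_rate = 2 * x + 1)
  expect_equal(r$rate_cor$r, 1)

  # bivariate normal with known correlation (constructed directly)
  set.seed(84)
  n <- 300
  rho <- 0.6
  z1 <- rnorm(n); z2 <- rnorm(n)
  adp <- 2.5 + 0.8 * z1
  rate <- 5 + 1.5 * (rho * z1 + sqrt(1 - rho^2) * z2)
  rr <- adp_firing_relationships(adp, mean_rate = rate)
  expect_lt(abs(rr$rate_cor$r - rho), 0.12)   # ~3 / sqrt(n)

  # anti-correlated latency: negative sign
  lat <- 2 - 0.3 * adp + rnorm(n, 0, 0.2)
  rl <- adp_firing_relationships(adp, onset_latency = lat)
  expect_lt(rl$latency_cor$r, 0)

  # a ~4 mV boundary separates firing from non-firing cells
  adp2 <- c(runif(20, 1, 3.8), runif(20, 4.2, 7))
  fired <- adp2 >= 4
  rb <- adp_firing_relationships(adp2, fired = fired)
  expect_gt(rb$boundary$threshold, 3.8)
  expect_lt(rb$boundary$threshold, 4.2)
  expect_equal(rb$boundary$accuracy, 1)

  expect_error(adp_firing_relationships(c(1, 2)), class = "pf_empty_input")
})

test_that("paired comparison: degenerate, extreme, and enumeration oracle", {
  p <- c(2.7, 3.1, 2.2, 4.0, 1.8, 2.9, 3.3, 2.4)
  same <- paired_condition_compare(p, p)
  expect_true(same$degenerate)
  expect_true(is.na(same$p_value))

  # post = pre - 1: all-negative differences, extreme statistic
  shift <- paired_condition_compare(p, p - 1)
  expect_equal(shift$W, -36)           # -(1+...+8)
  expect_equal(shift$p_value, 0.0078125, tolerance = 1e-6)  # 2 / 2^8

  # brute-force enumeration of all sign assignments, n <= 10
  set.seed(85)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    pre <- rnorm(n)
    post <- pre + rnorm(n, 0.3, 1)
    res <- paired_condition_compare(pre, post)
    d <- post - pre
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    V_all <- as.vector(signs %*% r)
    p_bf <- 2 * min(mean(V_all <= res$V), mean(V_all >= res$V))
    p_bf <- min(1, p_bf)
    expect_equal(res$p_value, p_bf, tolerance = 1e-10)
  }

  expect_error(paired_condition_compare(1:3, 1:4),
               class = "pf_length_mismatch")
})
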