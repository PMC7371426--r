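test_that("incidence rule: strictly after offset, inclusive at +10 s", {
  expect_true(classify_incidence(c(2.25 + 9.9), stim_offset = 2.25))
  expect_true(classify_incidence(c(12.25), stim_offset = 2.25))  # boundary
  expect_false(classify_incidence(c(0.5, 2.0), stim_offset = 2.25))
  expect_false(classify_incidence(c(12.75, 14.25), stim_offset = 2.25))
  expect_false(classify_incidence(numeric(0), stim_offset = 2.25))
  # brute-force window check over random spike sets
  set.seed(1)
  for (i in 1:50) {
    t <- sort(runif(sample(0:6, 1), 0, 20))
    expect_identical(classify_incidence(t, 2),
                     any(t > 2 & t <= 12))
  }
})

test_that("cell and group probability follow the proportion definitions", {
  expect_equal(cell_probability(c(TRUE, TRUE, FALSE)), 2 / 3,
               tolerance = 1e-12)
  expect_equal(cell_probability(c(TRUE, TRUE, TRUE)), 1)
  expect_error(cell_probability(logical(0)), class = "pf_empty_input")

  gp <- group_probability(rep(1, 22))
  expect_equal(gp$mean_pct, 100)
  expect_equal(gp$sem_pct, 0)

  gp2 <- group_probability(c(1, 0))
  expect_equal(gp2$mean_pct, 50)
  expect_equal(gp2$sem_pct, 50)
  expect_equal(gp2$median, 0.5)

  # brute-force mean + percentile oracle; invariance to ordering
  set.seed(2)
  for (i in 1:20) {
    p <- round(runif(sample(3:30, 1), 0, 3)) / 3
    gp3 <- group_probability(p)
    expect_equal(gp3$mean_pct, 100 * sum(p) / length(p))
    expect_equal(gp3$q1, bf_percentile(p, 0.25))
    expect_equal(gp3$median, bf_percentile(p, 0.5))
    expect_equal(gp3$q3, bf_percentile(p, 0.75))
    gp4 <- group_probability(sample(p))
    expect_equal(gp4[c("mean_pct", "q1", "median", "q3")],
                 gp3[c("mean_pct", "q1", "median", "q3")])
  }
})

test_that("binned rate bins, zero-fills, and conserves spike counts", {
  r <- binned_rate(2 + c(0.5, 1.5, 2.5), stim_offset = 2, sweep_end = 20)
  expect_equal(r[1:3], c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(sum(r[4:length(r)]), 0)
  expect_length(r, 18)

  z <- binned_rate(numeric(0), 2.25, 20)
  expect_true(all(z == 0))
  w <- attr(z, "widths")
  expect_equal(sum(w), 17.75)
  expect_equal(w[length(w)], 0.75)

  # conservation: sum(count) = number of post-offset spikes
  set.seed(3)
  for (i in 1:30) {
    t <- sort(runif(sample(0:80, 1), 0, 20))
    r <- binned_rate(t, 2, 20)
    expect_equal(sum(r * attr(r, "widths")), sum(t > 2 & t <= 20))
  }

  # Poisson oracle: constant 5 spikes/s
  set.seed(4)
  means <- replicate(400, {
    n <- rpois(1, 5 * 17)
    mean(binned_rate(2 + sort(runif(n, 0, 17)), 2, 19)[1:17])
  })
  expect_lt(abs(mean(means) - 5), 3 * sqrt(5 / 17 / 400))
})

test_that("mean rate averages bins per sweep then across sweeps", {
  b1 <- rep(2, 17); b2 <- rep(0, 17); b3 <- rep(0, 17)
  expect_equal(mean_rate(list(b1, b2, b3)), 2 / 3, tolerance = 1e-12)
  expect_equal(mean_rate(list(rep(4, 18), rep(4, 18), rep(4, 18))), 4)
  expect_error(mean_rate(list(b1), excluded = TRUE),
               class = "pf_excluded_cell")
})

test_that("onset latency averages firing sweeps only", {
  expect_equal(onset_latency(list(c(3.45)), 2.25), 1.2)
  expect_equal(onset_latency(list(c(3), c(4), numeric(0)), 2), 1.5)
  expect_error(onset_latency(list(numeric(0)), 2), class = "pf_empty_input")
  # spikes outside the incidence window do not define latency
  expect_error(onset_latency(list(c(13.5)), 2), class = "pf_empty_input")
})

test_that("exponential rise fit recovers noiseless parameters exactly", {
  t <- (0:17) + 0.5
  y <- 6 * (1 - exp(-t / 2))
  fit <- fit_rise(y)
  expect_true(fit$converged)
  expect_equal(fit$Ymax, 6, tolerance = 1e-6)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_length(fit$t, 9)             # bins fully inside 0-9 s

  # constant curve: Ymax -> c, tau -> small (near-degenerate)
  fitc <- fit_rise(rep(3, 18))
  expect_equal(fitc$Ymax, 3, tolerance = 1e-3)
  expect_lt(fitc$tau, 0.5)

  # fitted curve is nondecreasing for any positive parameters
  expect_true(all(diff(fit$fitted) >= 0))
  expect_true(all(diff(fitc$fitted) >= 0))
})

test_that("rise fit matches truth on random noiseless instances", {
  set.seed(6)
  for (i in 1:25) {
    Ymax <- runif(1, 1, 12); tau <- runif(1, 0.3, 8)
    y <- Ymax * (1 - exp(-((0:17) + 0.5) / tau))
    fit <- fit_rise(y)
    expect_lt(abs(fit$Ymax - Ymax) / Ymax, 0.01)
    expect_lt(abs(fit$tau - tau) / tau, 0.01)
  }
})

test_that("full pipeline recovers p_fire, tau, Ymax, latency on a clean cohort", {
  Ymax <- 6; tau <- 2; p_fire <- 0.67
  g <- generate_ephys_cohort(
    group_spec("YN", n_cells = 120, p_fire = p_fire, rate_Ymax = Ymax,
               rate_tau = tau, latency_mean = 0.3, latency_sd = 0.1),
    seed = 71, sample_rate = 2000, sweep_duration = 12, noise_sd = 0,
    include_ahp = FALSE, include_adp = FALSE)
  pt <- persistence_table(g$cohort, "train20hz_250ms_2mv")

  # p_fire within the binomial 95% CI over 360 sweeps
  n_sweeps <- sum(pt$table$n_sweeps)
  phat <- sum(pt$table$n_incidence) / n_sweeps
  expect_lt(abs(phat - p_fire), 1.96 * sqrt(p_fire * (1 - p_fire) / n_sweeps))

  # incidence flags equal the generator's intent exactly (no noise)
  truth <- g$truth$sweeps
  det <- unlist(lapply(pt$results, function(r) r$incidence))
  expect_equal(sum(det), sum(truth$n_persistent > 0 &
                               truth$first_persistent <= 2 + 10))

  # recovered latency equals the mean observable first-spike latency
  lat_truth <- truth$first_persistent[truth$fired &
                                        truth$n_persistent > 0] - 2
  lat_rec <- pt$table$onset_latency[!pt$table$excluded_from_rate]
  expect_equal(mean(lat_rec),
               mean(tapply(lat_truth,
                           truth$cell_id[truth$fired &
                                           truth$n_persistent > 0], mean)),
               tolerance = 0.02)
})

test_that("group mean rate matches the analytic time average at scale", {
  # law: rate Ymax(1-exp(-t/tau)) from t0 ~ 0; mean over [0, W] window
  Ymax <- 5; tau <- 1.5; W <- 10
  # 600 cells in chunks so tau's Poisson sampling error sits well inside
  # the 5% recovery bound; traces are discarded after analysis
  results <- list()
  rates <- numeric(0)
  for (chunk in 1:6) {
    g <- generate_ephys_cohort(
      group_spec("YN", n_cells = 100, p_fire = 1, rate_Ymax = Ymax,
                 rate_tau = tau, latency_mean = 0, latency_sd = 0),
      seed = 720 + chunk, sample_rate = 2000, sweep_duration = 12,
      noise_sd = 0, include_ahp = FALSE, include_adp = FALSE)
    pt <- persistence_table(g$cohort, "train20hz_250ms_2mv")
    results <- c(results, lapply(pt$results, function(r) {
      r$binned <- NULL  # keep only the per-cell curve
      r
    }))
    rates <- c(rates, pt$table$mean_rate)
    rm(g, pt)
  }
  # analytic expected count over the window, with crude refractory loss
  integral <- Ymax * (W - tau * (1 - exp(-W / tau)))
  analytic <- integral / W
  analytic_thinned <- analytic / (1 + Ymax * 0.004)
  se <- sqrt(Ymax / W / length(rates) / 3)
  expect_lt(abs(mean(rates) - analytic_thinned), 3 * se + 0.03 * analytic)

  # tau/Ymax recovered within 5% from the group mean curve (p_fire = 1 and
  # zero latency, so neither zero-fill scaling nor onset delay distorts the
  # curve shape)
  fit <- fit_rise(group_rate_curve(results))
  expect_lt(abs(fit$tau - tau) / tau, 0.05)
  expect_lt(abs(fit$Ymax - Ymax) / Ymax, 0.05)
})
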