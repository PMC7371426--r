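#' Ground-truth parameter set for one synthetic group
#'
#' Holds the per-group generative parameters the cohort simulator draws from:
#' per-sweep incidence probability, the asymptote and time constant of the
#' firing-rate rise, onset-latency moments, ADP/plateau and postburst-AHP
#' waveform moments, and per-session conditioned-response probabilities for
#' the behavioral simulator.
#'
#' @param group group label (YN, AN, YC, YP, AU, AI or other).
#' @param n_cells number of cells to simulate.
#' @param p_fire per-sweep persistent-firing incidence probability in \[0,1\].
#' @param rate_Ymax asymptotic firing rate, spikes/s.
#' @param rate_tau rise time constant, s (> 0).
#' @param latency_mean,latency_sd onset latency moments, s.
#' @param adp_peak_mean,adp_peak_sd ADP peak amplitude moments, mV.
#' @param pp_decay_tau plateau-potential decay time constant, s.
#' @param mahp_mean,mahp_sd medium AHP moments, mV (negative mean).
#' @param sahp_mean,sahp_sd slow AHP moments, mV (negative mean).
#' @param cr_prob_by_session five per-session CR probabilities in \[0,1\].
#' @param n_animals number of behavioral animals to simulate.
#' @return object of class `pf_group_spec`.
#' @export
group_spec <- function(group, n_cells = 10, p_fire = 1, rate_Ymax = 6,
                       rate_tau = 2.5, latency_mean = 1.5, latency_sd = 0.5,
                       adp_peak_mean = 2.5, adp_peak_sd = 0.8,
                       pp_decay_tau = 8, mahp_mean = -5.6, mahp_sd = 0.8,
                       sahp_mean = -3.6, sahp_sd = 0.9,
                       cr_prob_by_session = c(0.2, 0.35, 0.5, 0.6, 0.7),
                       n_animals = n_cells) {
  probs <- c(p_fire, cr_prob_by_session)
  assert_that(all(probs >= 0 & probs <= 1), "pf_bad_spec",
              "probabilities must lie in [0, 1]")
  assert_that(rate_tau > 0 && pp_decay_tau > 0, "pf_bad_spec",
              "time constants must be positive")
  assert_that(all(c(latency_sd, adp_peak_sd, mahp_sd, sahp_sd) >= 0),
              "pf_bad_spec", "sd parameters must be >= 0")
  assert_that(length(cr_prob_by_session) == 5, "pf_bad_spec",
              "cr_prob_by_session must give 5 session probabilities")
  structure(list(group = group, n_cells = n_cells, p_fire = p_fire,
                 rate_Ymax = rate_Ymax, rate_tau = rate_tau,
                 latency_mean = latency_mean, latency_sd = latency_sd,
                 adp_peak_mean = adp_peak_mean, adp_peak_sd = adp_peak_sd,
                 pp_decay_tau = pp_decay_tau, mahp_mean = mahp_mean,
                 mahp_sd = mahp_sd, sahp_mean = sahp_mean, sahp_sd = sahp_sd,
                 cr_prob_by_session = cr_prob_by_session,
                 n_animals = n_animals),
            class = "pf_group_spec")
}

#' Default six-group synthetic world
#'
#' A realistic parameterization of the six behavioral groups (young/aged x
#' naive/conditioned/pseudoconditioned/unimpaired/impaired) for the
#' 250 ms 20 Hz, 2-mV-below persistent-firing protocol: near-ceiling
#' incidence and fast rate rise for conditioned young animals, reduced
#' incidence/asymptote and longer latencies with aging and learning
#' impairment, and matching ADP/AHP and learning-curve parameters.
#'
#' @return named list of [group_spec()] objects.
#' @export
default_group_specs <- function() {
  list(
    YN = group_spec("YN", n_cells = 22, p_fire = 1.00, rate_Ymax = 6.4,
                    rate_tau = 2.66, latency_mean = 1.74, latency_sd = 0.9,
                    adp_peak_mean = 2.5, adp_peak_sd = 0.8,
                    mahp_mean = -5.6, sahp_mean = -3.6,
                    cr_prob_by_session = c(0, 0, 0, 0, 0)),
    AN = group_spec("AN", n_cells = 12, p_fire = 0.67, rate_Ymax = 4.2,
                    rate_tau = 4.72, latency_mean = 3.96, latency_sd = 1.5,
                    adp_peak_mean = 1.6, adp_peak_sd = 0.7,
                    mahp_mean = -6.8, sahp_mean = -4.3,
                    cr_prob_by_session = c(0, 0, 0, 0, 0)),
    YC = group_spec("YC", n_cells = 12, p_fire = 1.00, rate_Ymax = 10.9,
                    rate_tau = 1.60, latency_mean = 0.67, latency_sd = 0.25,
                    adp_peak_mean = 4.8, adp_peak_sd = 0.9,
                    mahp_mean = -4.3, sahp_mean = -2.2, n_animals = 21,
                    cr_prob_by_session = c(0.35, 0.5, 0.6, 0.68, 0.74)),
    YP = group_spec("YP", n_cells = 11, p_fire = 1.00, rate_Ymax = 7.8,
                    rate_tau = 2.24, latency_mean = 1.35, latency_sd = 0.6,
                    adp_peak_mean = 2.7, adp_peak_sd = 0.9,
                    mahp_mean = -5.7, sahp_mean = -3.3, n_animals = 19,
                    cr_prob_by_session = c(0.14, 0.15, 0.17, 0.18, 0.19)),
    AU = group_spec("AU", n_cells = 19, p_fire = 1.00, rate_Ymax = 7.0,
                    rate_tau = 2.50, latency_mean = 1.20, latency_sd = 0.5,
                    adp_peak_mean = 3.3, adp_peak_sd = 1.0,
                    mahp_mean = -5.4, sahp_mean = -3.1, n_animals = 21,
                    cr_prob_by_session = c(0.18, 0.3, 0.45, 0.58, 0.70)),
    AI = group_spec("AI", n_cells = 18, p_fire = 0.85, rate_Ymax = 5.5,
                    rate_tau = 3.46, latency_mean = 2.15, latency_sd = 1.4,
                    adp_peak_mean = 1.4, adp_peak_sd = 0.8,
                    mahp_mean = -8.2, sahp_mean = -4.8, n_animals = 16,
                    cr_prob_by_session = c(0.12, 0.15, 0.20, 0.25, 0.29))
  )
}

#' Stylized action-potential template
#'
#' A piecewise raised-cosine waveform added to the subthreshold trace at each
#' spike time: the upstroke rises `amplitude` mV over `rise_ms` with maximal
#' slope `amplitude * pi / (2 rise_ms)` V/s at half height, the downstroke
#' returns to baseline over `decay_ms`. Defaults put amplitude (~82 mV),
#' half-width (~2 ms) and dV/dt max (~184 V/s) in the range reported for
#' cortical pyramidal neurons, and the closed form makes detector features
#' checkable analytically.
#'
#' @param sample_rate Hz.
#' @param amplitude peak height above local baseline, mV.
#' @param rise_ms upstroke duration, ms.
#' @param decay_ms downstroke duration, ms.
#' @return list with `wave` (mV samples), `peak_idx` (1-based sample of the
#'   peak within `wave`) and the parameters.
#' @export
ap_template <- function(sample_rate, amplitude = 82, rise_ms = 0.7,
                        decay_ms = 3.3) {
  dt_ms <- 1000 / sample_rate
  t <- seq(dt_ms, rise_ms + decay_ms, by = dt_ms)
  up <- t <= rise_ms
  wave <- numeric(length(t))
  wave[up] <- amplitude / 2 * (1 - cos(pi * t[up] / rise_ms))
  wave[!up] <- amplitude / 2 * (1 + cos(pi * (t[!up] - rise_ms) / decay_ms))
  list(wave = wave, peak_idx = which.max(wave), amplitude = amplitude,
       rise_ms = rise_ms, decay_ms = decay_ms)
}

# Add template waveforms to `voltage` with peaks at `times` (s). Clips at
# the sweep boundaries.
insert_spikes <- function(voltage, times, template, sample_rate) {
  n <- length(voltage)
  for (tp in times) {
    peak_i <- round(tp * sample_rate) + 1L
    start <- peak_i - template$peak_idx + 1L
    idx <- start:(start + length(template$wave) - 1L)
    keep <- idx >= 1L & idx <= n
    voltage[idx[keep]] <- voltage[idx[keep]] + template$wave[keep]
  }
  voltage
}

# Inhomogeneous Poisson train with rate Ymax * (1 - exp(-(t - t0)/tau)) on
# (t0, t_end], thinned to a hard refractory period.
draw_persistent_spikes <- function(t0, t_end, Ymax, tau, refractory = 0.004) {
  if (t_end <= t0 || Ymax <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, Ymax * (t_end - t0))
  cand <- sort(stats::runif(n_cand, t0, t_end))
  lam <- 1 - exp(-(cand - t0) / tau)
  cand <- cand[stats::runif(n_cand) < lam]
  times <- numeric(0)
  last <- -Inf
  for (tc in cand) {
    if (tc - last >= refractory) {
      times <- c(times, tc)
      last <- tc
    }
  }
  times
}

# Evoked (stimulus-locked) spike times for a protocol: one AP per pulse for
# trains, a 25 Hz response for steps.
evoked_spike_times <- function(protocol) {
  if (protocol$kind == "step") {
    seq(protocol$stim_onset + 0.04, stim_offset(protocol) - 0.01, by = 0.04)
  } else {
    pulse_times(protocol) + 0.001
  }
}

synth_persistence_sweep <- function(protocol, threshold, fired, latency,
                                    Ymax, tau, adp_peak, pp_tau, noise_sd,
                                    sample_rate, duration, template) {
  n <- round(sample_rate * duration)
  t <- (seq_len(n) - 1L) / sample_rate
  holding <- threshold - protocol$holding_offset
  v <- rep(holding, n)
  off <- stim_offset(protocol)
  if (protocol$kind == "step") {
    # small subthreshold depolarizing envelope with 5 ms ramps, slope << the
    # detector's dV/dt criterion
    ramp <- pmin(1, pmax(0, (t - protocol$stim_onset) / 0.005)) *
      pmin(1, pmax(0, (off - t) / 0.005))
    v <- v + 8 * ramp
  }
  post <- t > off
  v[post] <- v[post] + adp_peak * exp(-(t[post] - off) / pp_tau)
  persistent <- numeric(0)
  if (fired) {
    t0 <- off + max(latency, 0)
    persistent <- draw_persistent_spikes(t0, duration - 0.01, Ymax, tau)
  }
  spikes <- c(evoked_spike_times(protocol), persistent)
  v <- insert_spikes(v, spikes, template, sample_rate)
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  list(voltage = v, persistent_times = persistent, holding = holding)
}

synth_ahp_sweep <- function(protocol, mahp, sahp, noise_sd, sample_rate,
                            duration, template, trough_time = 0.08,
                            rise_tau = 0.015) {
  n <- round(sample_rate * duration)
  t <- (seq_len(n) - 1L) / sample_rate
  holding <- protocol$absolute_holding
  v <- rep(holding, n)
  off <- stim_offset(protocol)
  # biexponential-style hyperpolarization: saturating approach to the trough
  # (minimum exactly `mahp` at off + trough_time), then exponential relaxation
  # pinned to `sahp` at off + 1 s
  sahp <- min(max(sahp, 0.95 * mahp), 0.05 * mahp)
  tau_d <- (1 - trough_time) / log(mahp / sahp)
  rel <- t - off
  early <- rel > 0 & rel <= trough_time
  late <- rel > trough_time
  v[early] <- v[early] + mahp * (1 - exp(-rel[early] / rise_tau)) /
    (1 - exp(-trough_time / rise_tau))
  v[late] <- v[late] + mahp * exp(-(rel[late] - trough_time) / tau_d)
  v <- insert_spikes(v, evoked_spike_times(protocol), template, sample_rate)
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  list(voltage = v, sahp_clipped = sahp, holding = holding)
}

#' Generate a synthetic electrophysiology cohort with ground truth
#'
#' Builds, per cell and persistent-firing protocol, three 20 s sweeps. With
#' probability `p_fire` a sweep persistently fires: spikes follow an
#' inhomogeneous Poisson process starting at `t0 = stimulus offset + drawn
#' latency` with rate `Ymax * (1 - exp(-(t - t0)/tau))`, thinned to a 4 ms
#' refractory period (so the observable onset latency is the drawn latency
#' plus the process's first waiting time).
#' All sweeps carry the ADP/plateau envelope (instantaneous rise to the drawn
#' peak, exponential decay with `pp_decay_tau`); stylized APs
#' ([ap_template()]) are inserted at evoked and persistent spike times, and
#' Gaussian noise of `noise_sd` mV is added throughout. Optional AHP-protocol
#' sweeps carry a 15-spike 50 Hz burst followed by a hyperpolarization whose
#' minimum equals the drawn mAHP and whose value 1 s post-burst equals the
#' drawn sAHP; optional ADP-protocol sweeps (held 10 mV below threshold)
#' contain the ADP envelope without persistent firing.
#'
#' The emitted `truth` tables are never read by analysis code; identical
#' seeds produce bit-identical cohorts.
#'
#' @param specs list of [group_spec()]; a single spec is accepted.
#' @param seed integer RNG seed.
#' @param protocols character names from [standard_protocols()] (or a named
#'   list of [pf_protocol()]) used as persistent-firing protocols.
#' @param include_ahp,include_adp add the AHP-burst / ADP protocols.
#' @param noise_sd voltage noise sd, mV.
#' @param sample_rate Hz (detector needs >= 2000).
#' @param sweep_duration persistent-firing sweep length, s.
#' @param ahp_sweep_duration,adp_sweep_duration sweep lengths, s.
#' @return list with elements `cohort` ([pf_cohort()]) and `truth` (list of
#'   data.tables: `cells`, `sweeps`).
#' @export
generate_ephys_cohort <- function(specs, seed,
                                  protocols = "train20hz_250ms_2mv",
                                  include_ahp = TRUE, include_adp = TRUE,
                                  noise_sd = 0.2, sample_rate = 10000,
                                  sweep_duration = 20,
                                  ahp_sweep_duration = 3,
                                  adp_sweep_duration = 20) {
  if (inherits(specs, "pf_group_spec")) specs <- list(specs)
  assert_that(sample_rate >= 2000, "pf_low_sample_rate",
              "sample_rate below 2 kHz cannot support spike detection")
  set.seed(as.integer(seed))
  catalog <- standard_protocols()
  if (is.character(protocols)) {
    assert_that(all(protocols %in% names(catalog)), "pf_bad_protocol",
                "unknown protocol name(s): %s",
                paste(setdiff(protocols, names(catalog)), collapse = ", "))
    protocols <- catalog[protocols]
  }
  template <- ap_template(sample_rate)
  cells <- list()
  truth_cells <- list()
  truth_sweeps <- list()
  for (spec in specs) {
    for (ci in seq_len(spec$n_cells)) {
      cell_id <- sprintf("%s_c%03d", spec$group, ci)
      threshold <- stats::rnorm(1, -42, 1)
      resting <- threshold - abs(stats::rnorm(1, 30, 1.5))
      rinput <- max(26, stats::rnorm(1, 55, 8))
      adp_peak <- max(0, stats::rnorm(1, spec$adp_peak_mean,
                                      spec$adp_peak_sd))
      mahp <- min(-0.5, stats::rnorm(1, spec$mahp_mean, spec$mahp_sd))
      sahp <- min(max(stats::rnorm(1, spec$sahp_mean, spec$sahp_sd),
                      0.95 * mahp), 0.05 * mahp)
      sweeps <- list()
      for (proto in protocols) {
        pname <- proto$name
        sweeps[[pname]] <- vector("list", proto$n_repeats)
        for (k in seq_len(proto$n_repeats)) {
          fired <- stats::runif(1) < spec$p_fire
          latency <- max(0, stats::rnorm(1, spec$latency_mean,
                                            spec$latency_sd))
          sy <- synth_persistence_sweep(proto, threshold, fired, latency,
                                        spec$rate_Ymax, spec$rate_tau,
                                        adp_peak, spec$pp_decay_tau,
                                        noise_sd, sample_rate,
                                        sweep_duration, template)
          sweeps[[pname]][[k]] <- pf_sweep(
            sy$voltage, sample_rate, proto, sweep_index = k,
            current = NULL, duration = sweep_duration)
          np <- length(sy$persistent_times)
          truth_sweeps[[length(truth_sweeps) + 1L]] <- data.table::data.table(
            cell_id = cell_id, group = spec$group, protocol = pname,
            sweep_index = k, fired = fired,
            latency = if (fired) latency else NA_real_,
            n_persistent = np,
            first_persistent = if (np) sy$persistent_times[1] else NA_real_,
            persistent_times = list(sy$persistent_times))
        }
      }
      if (include_adp) {
        proto <- catalog$adp_250ms_10mv
        sweeps[[proto$name]] <- lapply(seq_len(proto$n_repeats), function(k) {
          sy <- synth_persistence_sweep(proto, threshold, FALSE, NA,
                                        0, 1, adp_peak, spec$pp_decay_tau,
                                        noise_sd, sample_rate,
                                        adp_sweep_duration, template)
          pf_sweep(sy$voltage, sample_rate, proto, sweep_index = k,
                   duration = adp_sweep_duration)
        })
      }
      if (include_ahp) {
        proto <- catalog$ahp_burst50hz
        sweeps[[proto$name]] <- lapply(seq_len(proto$n_repeats), function(k) {
          sy <- synth_ahp_sweep(proto, mahp, sahp, noise_sd, sample_rate,
                                ahp_sweep_duration, template)
          pf_sweep(sy$voltage, sample_rate, proto, sweep_index = k,
                   duration = ahp_sweep_duration)
        })
      }
      cells[[cell_id]] <- pf_cell(cell_id, spec$group, threshold, resting,
                                  sweeps = sweeps,
                                  input_resistance = rinput,
                                  max_ap_height = template$amplitude)
      truth_cells[[length(truth_cells) + 1L]] <- data.table::data.table(
        cell_id = cell_id, group = spec$group, adp_peak = adp_peak,
        mahp = mahp, sahp = sahp, threshold = threshold)
    }
  }
  list(cohort = pf_cohort(cells = cells,
                          metadata = list(seed = as.integer(seed),
                                          noise_sd = noise_sd,
                                          sample_rate = sample_rate)),
       truth = list(cells = data.table::rbindlist(truth_cells),
                    sweeps = data.table::rbindlist(truth_sweeps)))
}
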