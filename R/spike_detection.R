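#' Detect action potentials and waveform features in a sweep
#'
#' An AP is registered where dV/dt crosses `dvdt_threshold` upward and the
#' voltage subsequently peaks at least `min_peak_above` mV above the crossing
#' point within `peak_window_ms`. Spike time is the AP peak; threshold is the
#' voltage at the dV/dt crossing; amplitude is peak minus threshold;
#' half-width is the width at threshold + amplitude/2; dV/dt max is the
#' maximal slope between crossing and peak. dV/dt is computed by central
#' differences on the raw trace (set `smooth_points` for an optional boxcar).
#' Spikes whose peak falls inside the stimulus window are tagged `evoked`;
#' only post-offset spikes count toward persistence metrics.
#'
#' @param sweep a [pf_sweep()].
#' @param dvdt_threshold V/s.
#' @param min_peak_above required peak height above the crossing, mV.
#' @param peak_window_ms search window for the peak after a crossing, ms.
#' @param smooth_points boxcar half-window (samples) applied before slope
#'   estimation; 0 disables smoothing.
#' @return a `pf_spike_train`: data.frame with columns `time` (s, at peak),
#'   `threshold`, `amplitude` (mV), `half_width` (ms), `dvdt_max` (V/s) and
#'   `evoked` (logical).
#' @section Errors: `pf_low_sample_rate` when the sweep is sampled below
#'   2 kHz (central differences cannot resolve the upstroke).
#' @export
detect_spikes <- function(sweep, dvdt_threshold = 20, min_peak_above = 20,
                          peak_window_ms = 5, smooth_points = 0) {
  assert_that(sweep$sample_rate >= 2000, "pf_low_sample_rate",
              "sample rate %g Hz too low to estimate dV/dt (need >= 2 kHz)",
              sweep$sample_rate)
  v <- sweep$voltage
  assert_that(all(is.finite(v)), "pf_bad_sweep",
              "voltage series contains non-finite values")
  if (smooth_points > 0) {
    k <- 2L * as.integer(smooth_points) + 1L
    v <- stats::filter(v, rep(1 / k, k), sides = 2)
    v[is.na(v)] <- sweep$voltage[is.na(v)]
    v <- as.numeric(v)
  }
  fs <- sweep$sample_rate
  n <- length(v)
  dt <- 1 / fs
  # central differences, V/s (= mV/ms)
  dvdt <- c(0, (v[3:n] - v[1:(n - 2)]) / (2 * dt) / 1000, 0)
  crossings <- which(dvdt[-1] >= dvdt_threshold &
                       dvdt[-n] < dvdt_threshold) + 1L
  win <- max(2L, round(peak_window_ms / 1000 * fs))
  out <- list()
  last_peak <- 0L
  last_time <- -Inf
  for (i in crossings) {
    if (i <= last_peak) next
    hi <- min(n, i + win)
    p <- i + which.max(v[i:hi]) - 1L
    if (v[p] - v[i] < min_peak_above) next
    tp <- (p - 1L) * dt
    if (tp - last_time < 0.002) next
    level <- v[i] + (v[p] - v[i]) / 2
    t_up <- interp_crossing(v, i, p, level, dt, up = TRUE)
    lim <- min(n, p + round(0.010 * fs))
    t_down <- interp_crossing(v, p, lim, level, dt, up = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      time = tp, threshold = v[i], amplitude = v[p] - v[i],
      half_width = if (is.na(t_down) || is.na(t_up)) NA_real_
                   else (t_down - t_up) * 1000,
      dvdt_max = max(dvdt[i:p]))
    last_peak <- p
    last_time <- tp
  }
  spikes <- if (length(out)) do.call(rbind, out) else
    data.frame(time = numeric(0), threshold = numeric(0),
               amplitude = numeric(0), half_width = numeric(0),
               dvdt_max = numeric(0))
  proto <- sweep$protocol
  spikes$evoked <- spikes$time >= proto$stim_onset &
    spikes$time <= stim_offset(proto)
  class(spikes) <- c("pf_spike_train", "data.frame")
  spikes
}

# Linear interpolation of the time (s) where v crosses `level` between
# samples a..b; NA when no crossing is found.
interp_crossing <- function(v, a, b, level, dt, up) {
  seg <- v[a:b]
  idx <- if (up) which(seg[-1] >= level & seg[-length(seg)] < level)
         else which(seg[-1] <= level & seg[-length(seg)] > level)
  if (!length(idx)) return(NA_real_)
  j <- a + idx[1] - 1L
  frac <- (level - v[j]) / (v[j + 1L] - v[j])
  (j - 1L + frac) * dt
}

#' Spike times occurring strictly after the stimulus offset
#' @param spikes a `pf_spike_train` from [detect_spikes()].
#' @param stim_offset stimulus offset time, s.
#' @return subset of `spikes`.
#' @export
post_offset_spikes <- function(spikes, stim_offset) {
  spikes[spikes$time > stim_offset, , drop = FALSE]
}

#' Waveform features of the first persistent-firing AP and the last AP
#'
#' Per sweep: the first spike after stimulus offset and the last spike
#' recorded in the sweep, with their features; plus cross-sweep means.
#' Sweeps without post-offset spikes contribute nothing; when no sweep has
#' any, an empty result (zero rows, NULL means) is returned rather than an
#' error.
#'
#' @param sweeps list of [pf_sweep()] (typically the 3 persistence sweeps).
#' @param ... passed to [detect_spikes()].
#' @return list with `per_sweep` (data.frame, one row per sweep and position
#'   `first`/`last`), `first_mean` and `last_mean` (named numeric vectors).
#' @export
ap_features_first_last <- function(sweeps, ...) {
  rows <- list()
  for (sw in sweeps) {
    spikes <- detect_spikes(sw, ...)
    post <- post_offset_spikes(spikes, stim_offset(sw$protocol))
    if (nrow(post) == 0) next
    first <- post[1, c("time", "threshold", "amplitude", "half_width",
                       "dvdt_max")]
    last <- spikes[nrow(spikes), c("time", "threshold", "amplitude",
                                   "half_width", "dvdt_max")]
    rows[[length(rows) + 1L]] <-
      cbind(sweep_index = sw$sweep_index,
            position = c("first", "last"), rbind(first, last))
  }
  if (!length(rows))
    return(list(per_sweep = data.frame(), first_mean = NULL,
                last_mean = NULL))
  per_sweep <- do.call(rbind, rows)
  rownames(per_sweep) <- NULL
  feat_cols <- c("threshold", "amplitude", "half_width", "dvdt_max")
  list(per_sweep = per_sweep,
       first_mean = colMeans(per_sweep[per_sweep$position == "first",
                                       feat_cols, drop = FALSE]),
       last_mean = colMeans(per_sweep[per_sweep$position == "last",
                                      feat_cols, drop = FALSE]))
}

#' Steady-state voltage response of a current-step sweep
#'
#' Mean membrane potential over a late window of the step (default
#' 700-900 ms after step onset, for 1 s steps), used as the steady-state
#' point of the input-resistance fit.
#'
#' @param sweep a [pf_sweep()].
#' @param stim_onset step onset, s; defaults to the sweep protocol's.
#' @param window two times (s, relative to onset) bounding the average.
#' @return scalar voltage, mV.
#' @export
steady_state_voltage <- function(sweep, stim_onset = NULL,
                                 window = c(0.7, 0.9)) {
  stim_onset <- stim_onset %||% sweep$protocol$stim_onset
  t <- sweep_time(sweep)
  sel <- t >= stim_onset + window[1] & t <= stim_onset + window[2]
  mean(sweep$voltage[sel])
}

#' Input resistance by ordinary least squares
#'
#' Fits steady-state voltage (mV) against injected current over a family of
#' hyperpolarizing steps; the slope in megaohm equals mV per nA.
#'
#' @param current_pA numeric vector of step currents, pA.
#' @param voltage_mV steady-state voltages, mV.
#' @return list of class `pf_rinput_fit`: `slope` (megaohm), `intercept`
#'   (mV), `r_squared`.
#' @section Errors: `pf_singular_fit` when fewer than two distinct current
#'   levels are supplied.
#' @export
input_resistance <- function(current_pA, voltage_mV) {
  assert_that(length(current_pA) == length(voltage_mV),
              "pf_length_mismatch", "current and voltage lengths differ")
  assert_that(length(unique(current_pA)) >= 2, "pf_singular_fit",
              "need >= 2 distinct current levels for the R_input fit")
  fit <- stats::lm(voltage_mV ~ current_pA)
  co <- stats::coef(fit)
  ss_tot <- sum((voltage_mV - mean(voltage_mV))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(slope = unname(co[2]) * 1000,  # mV/pA -> megaohm
                 intercept = unname(co[1]),
                 r_squared = r2),
            class = "pf_rinput_fit")
}
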