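boxcar_smooth <- function(x, k) {
  if (k <= 1) return(x)
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- x[is.na(sm)]
  as.numeric(sm)
}

#' Estimate the holding potential from the pre-stimulus baseline
#' @param sweep a [pf_sweep()].
#' @param window_s baseline length immediately preceding stimulus onset, s.
#' @export
estimate_holding <- function(sweep, window_s = 0.1) {
  t <- sweep_time(sweep)
  on <- sweep$protocol$stim_onset
  mean(sweep$voltage[t >= on - window_s & t < on])
}

#' Postburst AHP measurement for one sweep
#'
#' mAHP: minimum of the (lightly smoothed) membrane potential within
#' `mahp_window` after the burst offset, minus holding. sAHP: membrane
#' potential exactly 1 s after the burst offset, minus holding. Both are
#' negative for hyperpolarizations.
#'
#' @param sweep a [pf_sweep()] of the 15-pulse 50 Hz burst protocol.
#' @param burst_offset end of the last current step, s; defaults to the
#'   protocol's stimulus offset.
#' @param holding holding potential, mV; defaults to the protocol's
#'   `absolute_holding`, falling back to the pre-stimulus baseline.
#' @param mahp_window search window for the negative-going peak, s.
#' @param smooth_ms boxcar applied before locating the trough (suppresses
#'   the bias a raw pointwise minimum picks up from recording noise); 0
#'   disables.
#' @return list of class `pf_ahp`: `mAHP`, `sAHP` (mV), `holding`.
#' @section Errors: `pf_out_of_range` when `burst_offset + 1 s` lies past
#'   the sweep end.
#' @export
measure_ahp <- function(sweep, burst_offset = NULL, holding = NULL,
                        mahp_window = 0.5, smooth_ms = 5) {
  proto <- sweep$protocol
  burst_offset <- burst_offset %||% stim_offset(proto)
  assert_that(burst_offset + 1 <= sweep$duration + 1e-9, "pf_out_of_range",
              "burst_offset + 1 s (%.2f) exceeds sweep end (%.2f)",
              burst_offset + 1, sweep$duration)
  if (is.null(holding)) {
    holding <- if (is.finite(proto$absolute_holding)) proto$absolute_holding
               else estimate_holding(sweep)
  }
  v <- boxcar_smooth(sweep$voltage,
                     max(1L, round(smooth_ms / 1000 * sweep$sample_rate)))
  t <- sweep_time(sweep)
  trough_sel <- t > burst_offset & t <= burst_offset + mahp_window
  mAHP <- min(v[trough_sel]) - holding
  i1 <- which.min(abs(t - (burst_offset + 1)))
  sAHP <- v[i1] - holding
  structure(list(mAHP = mAHP, sAHP = sAHP, holding = holding),
            class = "pf_ahp")
}

#' Per-cell postburst AHP: sweep-averaged trace, then measurement
#'
#' Averages the voltage traces over the available sweeps (target five) and
#' measures the mAHP/sAHP on the averaged trace, plus per-sweep values for
#' reference.
#'
#' @param cell a [pf_cell()].
#' @param protocol AHP protocol name (default `"ahp_burst50hz"`).
#' @param ... passed to [measure_ahp()].
#' @return list: `mAHP`, `sAHP` (from the averaged trace), `per_sweep`
#'   (data.frame), `n_sweeps`.
#' @export
ahp_cell <- function(cell, protocol = "ahp_burst50hz", ...) {
  sweeps <- cell$sweeps[[protocol]]
  assert_that(length(sweeps) >= 1, "pf_missing_metadata",
              "cell %s has no %s sweeps", cell$cell_id, protocol)
  per <- do.call(rbind, lapply(sweeps, function(sw) {
    m <- measure_ahp(sw, ...)
    data.frame(sweep_index = sw$sweep_index, mAHP = m$mAHP, sAHP = m$sAHP)
  }))
  avg <- sweeps[[1]]
  avg$voltage <- rowMeans(vapply(sweeps, function(sw) sw$voltage,
                                 numeric(length(avg$voltage))))
  m <- measure_ahp(avg, ...)
  list(mAHP = m$mAHP, sAHP = m$sAHP, per_sweep = per,
       n_sweeps = length(sweeps))
}

#' ADP / plateau-potential measurement for one sweep
#'
#' Peak amplitude: maximum of the membrane potential within `peak_window`
#' after stimulus offset, minus holding. Area under the curve: trapezoidal
#' integral of (voltage - holding) from the stimulus offset to `window_end`,
#' in mV*ms (may be negative where the trace dips below holding). The
#' protocol holds the cell 10 mV below spontaneous firing threshold so no
#' post-offset spikes should occur; detected ones raise a contamination
#' error.
#'
#' @param sweep a [pf_sweep()].
#' @param stim_offset_s stimulus offset, s; defaults to the protocol's.
#' @param holding mV; defaults to the pre-stimulus baseline estimate.
#' @param peak_window peak search window, s.
#' @param window_end AUC integration end, s; defaults to the sweep end.
#' @param smooth_ms boxcar before the peak search; 0 disables.
#' @param check_spikes run the spike detector to guard against firing.
#' @return list of class `pf_adp`: `adp_peak` (mV), `auc` (mV*ms),
#'   `integration_window`, `holding`.
#' @section Errors: `pf_spike_contamination` when post-offset APs are found.
#' @export
measure_adp <- function(sweep, stim_offset_s = NULL, holding = NULL,
                        peak_window = 2, window_end = NULL, smooth_ms = 5,
                        check_spikes = TRUE) {
  off <- stim_offset_s %||% stim_offset(sweep$protocol)
  window_end <- window_end %||% sweep$duration
  holding <- holding %||% estimate_holding(sweep)
  if (check_spikes) {
    post <- post_offset_spikes(detect_spikes(sweep), off)
    assert_that(nrow(post) == 0, "pf_spike_contamination",
                "%d post-offset action potential(s); ADP protocol precludes firing",
                nrow(post))
  }
  t <- sweep_time(sweep)
  vs <- boxcar_smooth(sweep$voltage,
                      max(1L, round(smooth_ms / 1000 * sweep$sample_rate)))
  peak_sel <- t > off & t <= off + peak_window
  adp_peak <- max(vs[peak_sel]) - holding
  int_sel <- which(t > off & t <= window_end)
  dv <- sweep$voltage[int_sel] - holding
  dt_ms <- 1000 / sweep$sample_rate
  auc <- if (length(dv) > 1)
    sum((dv[-1] + dv[-length(dv)]) / 2) * dt_ms else 0
  structure(list(adp_peak = adp_peak, auc = auc,
                 integration_window = c(off, window_end), holding = holding),
            class = "pf_adp")
}

#' Per-cell ADP: mean of per-sweep measurements
#' @param cell a [pf_cell()].
#' @param protocol ADP protocol name (default `"adp_250ms_10mv"`).
#' @param ... passed to [measure_adp()].
#' @return list: `adp_peak`, `auc` (cross-sweep means), `per_sweep`,
#'   `n_sweeps`.
#' @export
adp_cell <- function(cell, protocol = "adp_250ms_10mv", ...) {
  sweeps <- cell$sweeps[[protocol]]
  assert_that(length(sweeps) >= 1, "pf_missing_metadata",
              "cell %s has no %s sweeps", cell$cell_id, protocol)
  per <- do.call(rbind, lapply(sweeps, function(sw) {
    m <- measure_adp(sw, ...)
    data.frame(sweep_index = sw$sweep_index, adp_peak = m$adp_peak,
               auc = m$auc)
  }))
  list(adp_peak = mean(per$adp_peak), auc = mean(per$auc), per_sweep = per,
       n_sweeps = length(sweeps))
}

#' Relationships between ADP size and persistent-firing behavior
#'
#' Pearson correlations of ADP peak with mean firing rate and with onset
#' latency, and a threshold scan for the ADP amplitude that best separates
#' firing from non-firing cells (the boundary phenomenon observed under the
#' 5-mV-below holding condition).
#'
#' @param adp_peak per-cell ADP peaks, mV.
#' @param mean_rate per-cell mean rates, spikes/s (NA allowed).
#' @param onset_latency per-cell latencies, s (NA allowed).
#' @param fired per-cell logical (probability > 0) for the threshold scan.
#' @return list: `rate_cor`, `latency_cor` (each a `pf_test`), `boundary`
#'   (list with `threshold`, `accuracy`) or NULL when `fired` is absent.
#' @export
adp_firing_relationships <- function(adp_peak, mean_rate = NULL,
                                     onset_latency = NULL, fired = NULL) {
  assert_that(length(adp_peak) >= 3, "pf_empty_input",
              "need >= 3 paired cells")
  out <- list(rate_cor = NULL, latency_cor = NULL, boundary = NULL)
  pair_cor <- function(y) {
    ok <- is.finite(adp_peak) & is.finite(y)
    pearson_cor(adp_peak[ok], y[ok])
  }
  if (!is.null(mean_rate)) out$rate_cor <- pair_cor(mean_rate)
  if (!is.null(onset_latency)) out$latency_cor <- pair_cor(onset_latency)
  if (!is.null(fired)) {
    cand <- sort(unique(adp_peak))
    cand <- (cand[-1] + cand[-length(cand)]) / 2
    acc <- vapply(cand, function(th)
      mean((adp_peak >= th) == as.logical(fired)), numeric(1))
    best <- which.max(acc)
    out$boundary <- list(threshold = cand[best], accuracy = acc[best])
  }
  out
}

#' Paired pre/post condition comparison (Wilcoxon signed rank)
#'
#' Computes paired differences (post - pre), the signed-rank statistic
#' W = (sum of positive ranks) - (sum of negative ranks) of the nonzero
#' differences, and a two-sided p-value: exact (signed-rank distribution)
#' for n <= 20 without ties in |differences|, normal approximation
#' otherwise. All-zero differences yield a degenerate report, not an error.
#'
#' @param pre,post equal-length paired per-cell values.
#' @return list of class `pf_paired`: `n`, `n_used`, `W`, `V`, `p_value`,
#'   `mean_pre`, `mean_post`, `mean_diff`, `degenerate`, `method`.
#' @export
paired_condition_compare <- function(pre, post) {
  assert_that(length(pre) == length(post), "pf_length_mismatch",
              "pre and post must be paired (lengths %d vs %d)",
              length(pre), length(post))
  d <- post - pre
  dn <- d[d != 0]
  n <- length(dn)
  base <- list(n = length(d), n_used = n, mean_pre = mean(pre),
               mean_post = mean(post), mean_diff = mean(d))
  if (n == 0)
    return(structure(c(base, list(W = 0, V = 0, p_value = NA_real_,
                                  degenerate = TRUE, method = "none")),
                     class = "pf_paired"))
  r <- rank(abs(dn))
  V <- sum(r[dn > 0])
  W <- V - sum(r[dn < 0])
  ties <- any(duplicated(abs(dn)))
  if (n <= 14) {
    # exact two-sided p by enumeration of all 2^n sign assignments
    # (midranks make this valid under ties as well)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    V_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(V_all <= V), mean(V_all >= V)))
    method <- "exact"
  } else if (n <= 20 && !ties) {
    # exact two-sided p from the null signed-rank distribution of V
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(tie_tab^3 - tie_tab) / 48)
    z <- (V - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(c(base, list(W = W, V = V, p_value = p, degenerate = FALSE,
                         method = method)),
            class = "pf_paired")
}
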