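spike_time_vector <- function(spikes) {
  if (is.data.frame(spikes)) spikes$time else as.numeric(spikes)
}

#' Classify persistent-firing incidence for one sweep
#'
#' A sweep counts as an incidence of persistent firing iff at least one spike
#' falls strictly after the stimulus offset and no later than `window`
#' seconds after it (half-open at the offset, inclusive at offset + window).
#'
#' @param spikes a `pf_spike_train` or numeric spike times, s.
#' @param stim_offset end of the current injection, s.
#' @param window incidence window length, s (study rule: 10 s).
#' @return logical scalar.
#' @export
classify_incidence <- function(spikes, stim_offset, window = 10) {
  t <- spike_time_vector(spikes)
  any(t > stim_offset & t <= stim_offset + window)
}

#' Per-cell firing probability: proportion of sweeps with incidence
#' @param incidences logical vector, one element per recorded sweep (1-3).
#' @return fraction in \[0, 1\].
#' @export
cell_probability <- function(incidences) {
  assert_that(length(incidences) >= 1, "pf_empty_input",
              "no recorded sweeps")
  mean(as.logical(incidences))
}

#' Group persistent-firing probability summary
#'
#' Mean of the per-cell proportions expressed as a percentage with its SEM,
#' plus the 25/50/75 percentiles of the per-cell proportions (linear
#' interpolation).
#'
#' @param probabilities per-cell proportions in \[0, 1\].
#' @return list: `n`, `mean_pct`, `sem_pct`, `q1`, `median`, `q3`.
#' @export
group_probability <- function(probabilities) {
  assert_that(length(probabilities) >= 1, "pf_empty_input", "no cells")
  p <- as.numeric(probabilities)
  qs <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(p), mean_pct = 100 * mean(p),
       sem_pct = 100 * stats::sd(p) / sqrt(length(p)),
       q1 = qs[1], median = qs[2], q3 = qs[3])
}

#' Binned post-offset firing rate for one sweep
#'
#' Bin k (k = 0, 1, ...) counts spikes in \[offset + k, offset + k + 1) s;
#' empty bins are 0. The window runs from the stimulus offset to the sweep
#' end, so the final bin may be partial; its value is count / width
#' (spikes/s) and bin widths are attached as the `"widths"` attribute.
#'
#' @param spikes a `pf_spike_train` or numeric spike times, s.
#' @param stim_offset stimulus offset, s.
#' @param sweep_end sweep duration, s.
#' @param bin_width bin width, s.
#' @return numeric rate vector (spikes/s) with a `"widths"` attribute.
#' @export
binned_rate <- function(spikes, stim_offset, sweep_end, bin_width = 1) {
  t <- spike_time_vector(spikes)
  t <- t[t > stim_offset & t <= sweep_end]
  window <- sweep_end - stim_offset
  n_full <- floor(window / bin_width + 1e-9)
  widths <- rep(bin_width, n_full)
  partial <- window - n_full * bin_width
  if (partial > 1e-9) widths <- c(widths, partial)
  edges <- stim_offset + c(0, cumsum(widths))
  counts <- if (length(t))
    as.numeric(table(cut(t, breaks = edges, right = FALSE)))
  else numeric(length(widths))
  rate <- counts / widths
  attr(rate, "widths") <- widths
  rate
}

bin_widths_of <- function(v) attr(v, "widths") %||% rep(1, length(v))

#' Cross-sweep mean firing rate
#'
#' Per sweep: the time-weighted mean over all post-offset bins (zero-filled
#' non-firing sweeps included); cell value: mean across sweeps.
#'
#' @param binned list of per-sweep rate vectors from [binned_rate()].
#' @param excluded set TRUE for a 0%-probability cell to get the
#'   documented named error instead of a meaningless 0.
#' @return spikes/s.
#' @section Errors: `pf_excluded_cell` when `excluded` is TRUE; callers
#'   should skip such cells (the rate analysis excludes 0%-probability
#'   cells).
#' @export
mean_rate <- function(binned, excluded = FALSE) {
  assert_that(!isTRUE(excluded), "pf_excluded_cell",
              "cell has 0%% firing probability; excluded from rate analysis")
  per_sweep <- vapply(binned, function(v) {
    w <- bin_widths_of(v)
    sum(v * w) / sum(w)
  }, numeric(1))
  mean(per_sweep)
}

#' Onset latency of persistent firing
#'
#' Per firing sweep: time of the first post-offset spike minus the stimulus
#' offset; cell value: mean over firing sweeps only (non-firing sweeps carry
#' no latency).
#'
#' @param spike_lists list of per-sweep spike trains or time vectors.
#' @param stim_offset stimulus offset, s.
#' @param window incidence window used to decide "firing", s.
#' @return mean latency, s.
#' @section Errors: `pf_empty_input` when no sweep fired.
#' @export
onset_latency <- function(spike_lists, stim_offset, window = 10) {
  lat <- vapply(spike_lists, function(sp) {
    t <- spike_time_vector(sp)
    t <- t[t > stim_offset & t <= stim_offset + window]
    if (length(t)) t[1] - stim_offset else NA_real_
  }, numeric(1))
  lat <- lat[!is.na(lat)]
  assert_that(length(lat) >= 1, "pf_empty_input", "no firing sweeps")
  mean(lat)
}

#' One-phase exponential rise fit to a rate curve
#'
#' Nonlinear least squares of `Y(t) = Ymax * (1 - exp(-t / tau))` against
#' bin-center times `t = k + 0.5` s over the bins falling inside the fit
#' window (default the 0-9 s rising phase). Initialization uses the maximal
#' observed bin and tau = 2 s, with up to `restarts` jittered restarts and a
#' coarse grid fallback; non-convergence returns `converged = FALSE` with
#' the best grid point instead of raising.
#'
#' @param rates rate curve, spikes/s, one value per 1 s bin anchored at the
#'   stimulus offset (bin k covers \[k, k+1) s post-offset).
#' @param window fit window, s post-offset; bins fully inside are used.
#' @param restarts maximal jittered restarts of the optimizer.
#' @return object of class `pf_rate_fit`: `Ymax`, `tau` (s), `rss`,
#'   `converged`, `t` and `fitted`.
#' @export
fit_rise <- function(rates, window = c(0, 9), restarts = 5) {
  k <- seq_along(rates) - 1L
  keep <- k >= window[1] & (k + 1) <= window[2] + 1e-9
  y <- as.numeric(rates[keep])
  t <- k[keep] + 0.5
  assert_that(length(y) >= 3, "pf_empty_input",
              "need >= 3 bins inside the fit window")
  ymax0 <- max(y, 1e-6)
  one_try <- function(start) {
    tryCatch({
      fit <- stats::nls(y ~ Ymax * (1 - exp(-t / tau)),
                        start = start, algorithm = "port",
                        lower = c(Ymax = 1e-9, tau = 0.05),
                        upper = c(Ymax = 10 * ymax0, tau = 50),
                        control = stats::nls.control(maxiter = 200,
                                                     warnOnly = FALSE))
      co <- stats::coef(fit)
      list(Ymax = unname(co["Ymax"]), tau = unname(co["tau"]),
           rss = sum(stats::resid(fit)^2), ok = TRUE)
    }, error = function(e) NULL)
  }
  best <- one_try(list(Ymax = ymax0, tau = 2))
  i <- 0
  while (is.null(best) && i < restarts) {
    i <- i + 1
    best <- one_try(list(Ymax = ymax0 * stats::runif(1, 0.5, 2),
                         tau = exp(stats::runif(1, log(0.1), log(20)))))
  }
  if (is.null(best)) {
    grid <- expand.grid(Ymax = ymax0 * seq(0.2, 3, length.out = 40),
                        tau = exp(seq(log(0.05), log(50), length.out = 60)))
    rss <- vapply(seq_len(nrow(grid)), function(j)
      sum((y - grid$Ymax[j] * (1 - exp(-t / grid$tau[j])))^2), numeric(1))
    j <- which.min(rss)
    best <- list(Ymax = grid$Ymax[j], tau = grid$tau[j], rss = rss[j],
                 ok = FALSE)
  }
  structure(list(Ymax = best$Ymax, tau = best$tau, rss = best$rss,
                 converged = isTRUE(best$ok), t = t,
                 fitted = best$Ymax * (1 - exp(-t / best$tau))),
            class = "pf_rate_fit")
}

#' @export
print.pf_rate_fit <- function(x, ...) {
  cat(sprintf("<pf_rate_fit> Ymax = %.3f spikes/s, tau = %.3f s (rss %.4g%s)\n",
              x$Ymax, x$tau, x$rss,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Full persistence analysis of one cell under one protocol
#'
#' Runs spike detection over the cell's sweeps for `protocol`, applies the
#' incidence rule, and assembles the per-cell summary: per-sweep incidence,
#' firing probability, onset latency (firing sweeps only), zero-filled
#' binned rates, cross-sweep mean rate, and the peak of the sweep-averaged
#' rate curve. Cells with 0% probability are flagged `excluded_from_rate`
#' and carry NA rate fields.
#'
#' @param cell a [pf_cell()].
#' @param protocol protocol name present in `cell$sweeps`.
#' @param incidence_window s, study rule 10 s.
#' @param ... passed to [detect_spikes()].
#' @return object of class `pf_persistence`: fields `cell_id`, `group`,
#'   `incidence`, `probability`, `onset_latency`, `binned`, `mean_rate`,
#'   `peak_rate`, `peak_bin`, `excluded_from_rate`.
#' @export
analyze_persistence <- function(cell, protocol, incidence_window = 10, ...) {
  sweeps <- cell$sweeps[[protocol]]
  assert_that(!is.null(sweeps) && length(sweeps) >= 1, "pf_missing_metadata",
              "cell %s has no sweeps for protocol %s", cell$cell_id, protocol)
  off <- stim_offset(sweeps[[1]]$protocol)
  trains <- lapply(sweeps, function(sw) {
    post_offset_spikes(detect_spikes(sw, ...), off)
  })
  incidence <- vapply(trains, classify_incidence, logical(1),
                      stim_offset = off, window = incidence_window)
  prob <- cell_probability(incidence)
  binned <- lapply(seq_along(trains), function(i) {
    if (incidence[i])
      binned_rate(trains[[i]], off, sweeps[[i]]$duration)
    else {
      # zero-fill rule: non-firing sweeps of a partially firing cell
      z <- binned_rate(numeric(0), off, sweeps[[i]]$duration)
      z
    }
  })
  excluded <- prob == 0
  if (!excluded) {
    mr <- mean_rate(binned)
    wmin <- min(vapply(binned, length, integer(1)))
    curve <- rowMeans(vapply(binned, function(v) v[seq_len(wmin)],
                             numeric(wmin)))
    peak_bin <- which.max(curve)
    peak_rate <- curve[peak_bin]
    lat <- onset_latency(trains, off, incidence_window)
  } else {
    mr <- NA_real_; peak_bin <- NA_integer_; peak_rate <- NA_real_
    lat <- NA_real_; curve <- NULL
  }
  structure(list(cell_id = cell$cell_id, group = cell$group,
                 incidence = incidence, probability = prob,
                 onset_latency = lat, binned = binned, rate_curve = curve,
                 mean_rate = mr, peak_rate = peak_rate, peak_bin = peak_bin,
                 excluded_from_rate = excluded, stim_offset = off),
            class = "pf_persistence")
}

#' Per-cell persistence metrics for a whole cohort
#'
#' @param cohort a [pf_cohort()].
#' @param protocol protocol name to analyze.
#' @param ... passed to [analyze_persistence()].
#' @return list with `table` (data.table, one row per cell) and `results`
#'   (list of `pf_persistence`).
#' @export
persistence_table <- function(cohort, protocol, ...) {
  cells <- Filter(function(cl) protocol %in% names(cl$sweeps), cohort$cells)
  results <- lapply(cells, analyze_persistence, protocol = protocol, ...)
  tab <- data.table::rbindlist(lapply(results, function(r)
    data.table::data.table(cell_id = r$cell_id, group = r$group,
                           n_sweeps = length(r$incidence),
                           n_incidence = sum(r$incidence),
                           probability = r$probability,
                           onset_latency = r$onset_latency,
                           mean_rate = r$mean_rate, peak_rate = r$peak_rate,
                           peak_bin = r$peak_bin,
                           excluded_from_rate = r$excluded_from_rate)))
  list(table = tab, results = results)
}

#' Cross-cell mean rate curve of a group
#'
#' Averages the per-cell sweep-averaged binned-rate curves over the
#' non-excluded cells of one group; this is the curve the exponential rise
#' is fitted to.
#'
#' @param results list of `pf_persistence` (e.g. from [persistence_table()]).
#' @param group optional group label filter.
#' @return numeric rate vector (bins anchored at stimulus offset).
#' @export
group_rate_curve <- function(results, group = NULL) {
  keep <- Filter(function(r) {
    !r$excluded_from_rate && (is.null(group) || identical(r$group, group))
  }, results)
  assert_that(length(keep) >= 1, "pf_empty_input",
              "no non-excluded cells in group")
  wmin <- min(vapply(keep, function(r) length(r$rate_curve), integer(1)))
  rowMeans(vapply(keep, function(r) r$rate_curve[seq_len(wmin)],
                  numeric(wmin)))
}
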