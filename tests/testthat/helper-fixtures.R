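# Shared fixtures. Oracles here are written against the mathematical
# definitions (closed forms, brute force, independent simulation), not
# against the package's implementation paths.

# ---- analytic oracle for the raised-cosine AP template -------------------
# v_up(t)   = A/2 (1 - cos(pi t / r)),        t in [0, r]    (ms)
# v_down(t) = A/2 (1 + cos(pi (t - r) / d)),  t in [r, r+d]
# slope (V/s = mV/ms): up A pi/(2r) sin(pi t/r); max = A pi / (2 r).
template_oracle <- function(A = 82, rise_ms = 0.7, decay_ms = 3.3,
                            dvdt_thr = 20) {
  s_max <- A * pi / (2 * rise_ms)
  t_cross <- rise_ms / pi * asin(dvdt_thr / s_max)
  v_cross <- A / 2 * (1 - cos(pi * t_cross / rise_ms))   # above base
  amplitude <- A - v_cross
  level <- v_cross + amplitude / 2                        # above base
  t_up <- rise_ms / pi * acos(1 - 2 * level / A)
  t_down <- rise_ms + decay_ms / pi * acos(2 * level / A - 1)
  list(threshold_offset = v_cross, amplitude = amplitude,
       half_width = t_down - t_up, dvdt_max = s_max)
}

# place template waves onto a baseline trace (peak at `times`, s);
# deliberately re-derived from the closed form rather than calling package
# insertion code
build_trace_with_aps <- function(times, fs = 10000, duration = 5,
                                 base = -70, A = 82, rise_ms = 0.7,
                                 decay_ms = 3.3) {
  n <- round(fs * duration)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  v <- rep(base, n)
  for (tp in times) {
    start_ms <- tp * 1000 - rise_ms
    rel <- t_ms - start_ms
    up <- rel > 0 & rel <= rise_ms
    down <- rel > rise_ms & rel <= rise_ms + decay_ms
    v[up] <- v[up] + A / 2 * (1 - cos(pi * rel[up] / rise_ms))
    v[down] <- v[down] + A / 2 * (1 + cos(pi * (rel[down] - rise_ms) /
                                            decay_ms))
  }
  v
}

flat_sweep <- function(level = -70, fs = 10000, duration = 5,
                       protocol = NULL) {
  protocol <- protocol %||%
    pf_protocol("step", step_amplitude = 100, step_duration = 0.5,
                stim_onset = 0.25, name = "teststep")
  pf_sweep(rep(level, round(fs * duration)), fs, protocol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_specs <- function(n_cells = 2, ...) {
  group_spec("YN", n_cells = n_cells, p_fire = 1, rate_Ymax = 5,
             rate_tau = 2, latency_mean = 1, latency_sd = 0.3, ...)
}

tiny_cohort <- function(seed = 1, n_cells = 2, with_behavior = FALSE, ...) {
  g <- generate_ephys_cohort(tiny_specs(n_cells), seed = seed,
                             sample_rate = 2000, sweep_duration = 6,
                             adp_sweep_duration = 4, ...)
  if (with_behavior) {
    b <- generate_behavior_cohort(
      group_spec("YC", n_animals = 2,
                 cr_prob_by_session = c(0.2, 0.3, 0.4, 0.5, 0.6)),
      seed = seed + 1)
    g$cohort$animals <- b$animals
  }
  g
}

# ---- ABF1 writer (independent of the package reader) ---------------------
# Written from the published ABF1 header layout: 2048-byte header, data at
# lDataSectionPtr * 512, int16 or float32 samples interleaved by channel.
write_abf1 <- function(path, episodes, sample_rate, channel_names,
                       channel_units = NULL, data_format = 1L,
                       operation_mode = 5L, version = 1.83,
                       adc_range = 10, adc_resolution = 32768L,
                       signature = "ABF ") {
  nch <- length(channel_names)
  channel_units <- channel_units %||% rep("mV", nch)
  n_ep <- length(episodes)
  per_chan <- nrow(episodes[[1]])
  samples_per_ep <- per_chan * nch
  header <- raw(2048)
  put <- function(offset, value, what, size) {
    b <- writeBin(value, raw(), size = size, endian = "little")
    header[(offset + 1):(offset + length(b))] <<- b
  }
  put_chr <- function(offset, s, width) {
    b <- charToRaw(formatC(s, width = -width))[seq_len(width)]
    header[(offset + 1):(offset + width)] <<- b
  }
  put_chr(0, signature, 4)
  put(4, as.numeric(version), "double", 4)
  put(8, as.integer(operation_mode), "integer", 2)
  put(10, as.integer(samples_per_ep * n_ep), "integer", 4)
  put(16, as.integer(n_ep), "integer", 4)
  put(40, 4L, "integer", 4)                 # data at block 4 = byte 2048
  put(100, as.integer(data_format), "integer", 2)
  put(120, as.integer(nch), "integer", 2)
  put(122, 1e6 / (sample_rate * nch), "double", 4)
  put(138, as.integer(samples_per_ep), "integer", 4)
  put(244, adc_range, "double", 4)
  put(252, as.integer(adc_resolution), "integer", 4)
  for (i in seq_len(nch)) {
    put_chr(442 + (i - 1) * 10, channel_names[i], 10)
    put_chr(602 + (i - 1) * 8, channel_units[i], 8)
  }
  for (i in 1:16) {
    put(730 + (i - 1) * 4, 1, "double", 4)   # programmable gain
    put(922 + (i - 1) * 4, 1, "double", 4)   # instrument scale
    put(986 + (i - 1) * 4, 0, "double", 4)   # instrument offset
    put(1050 + (i - 1) * 4, 1, "double", 4)  # signal gain
    put(1114 + (i - 1) * 4, 0, "double", 4)  # signal offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (ep in episodes) {
    interleaved <- as.vector(t(as.matrix(ep)))   # sample-major, ch minor
    if (data_format == 0L) {
      writeBin(as.integer(round(interleaved * adc_resolution / adc_range)),
               con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(interleaved), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

# brute-force type-7 percentile (sort + linear interpolation)
bf_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
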