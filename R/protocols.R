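#' Stimulus protocol descriptor
#'
#' A `pf_protocol` records the command waveform used to evoke activity in one
#' family of sweeps: a rectangular current step, a train of brief
#' suprathreshold pulses, or the 15-pulse 50 Hz burst used to evoke the
#' postburst AHP. Holding is expressed either as an offset below the cell's
#' spontaneous firing threshold (`holding_offset`, in mV; the convention for
#' persistent-firing and ADP protocols) or as an absolute potential
#' (`absolute_holding`, used for the AHP burst which is delivered near rest).
#'
#' @param kind one of `"step"`, `"pulse_train"`, `"ahp_burst"`.
#' @param step_amplitude step current in pA (kind `"step"`).
#' @param step_duration step length in seconds (kind `"step"`).
#' @param pulse_amplitude_nA pulse current in nA (pulse kinds).
#' @param pulse_width_ms single pulse width in ms.
#' @param pulse_frequency pulse rate in Hz.
#' @param train_duration pulse-train length in seconds.
#' @param holding_offset mV below the cell's spontaneous firing threshold at
#'   which the membrane is held; 0 means `absolute_holding` applies instead.
#' @param absolute_holding absolute holding potential in mV (AHP burst).
#' @param stim_onset stimulus onset, seconds from sweep start.
#' @param n_repeats how many sweeps this protocol is evoked per cell.
#' @param name optional short label.
#' @return an object of class `pf_protocol`.
#' @export
pf_protocol <- function(kind = c("step", "pulse_train", "ahp_burst"),
                        step_amplitude = NA_real_, step_duration = NA_real_,
                        pulse_amplitude_nA = 2, pulse_width_ms = 2,
                        pulse_frequency = 20, train_duration = NA_real_,
                        holding_offset = 0, absolute_holding = NA_real_,
                        stim_onset = 0.25, n_repeats = 3, name = NULL) {
  kind <- match.arg(kind)
  if (kind == "step") {
    assert_that(is.finite(step_amplitude) && is.finite(step_duration) &&
                  step_duration > 0,
                "pf_bad_protocol", "step protocols need amplitude and duration")
  } else {
    assert_that(is.finite(train_duration) && train_duration > 0 &&
                  pulse_width_ms > 0 && pulse_frequency > 0,
                "pf_bad_protocol",
                "pulse protocols need positive width, frequency and duration")
  }
  assert_that(stim_onset >= 0, "pf_bad_protocol", "stim_onset must be >= 0")
  structure(list(
    kind = kind, step_amplitude = step_amplitude,
    step_duration = step_duration, pulse_amplitude_nA = pulse_amplitude_nA,
    pulse_width_ms = pulse_width_ms, pulse_frequency = pulse_frequency,
    train_duration = train_duration, holding_offset = holding_offset,
    absolute_holding = absolute_holding, stim_onset = stim_onset,
    n_repeats = n_repeats,
    name = name %||% kind
  ), class = "pf_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stimulus duration of a protocol, in seconds
#' @param protocol a [pf_protocol()].
#' @export
stim_duration <- function(protocol) {
  if (protocol$kind == "step") protocol$step_duration else protocol$train_duration
}

#' Stimulus offset time (end of the current injection), seconds from sweep start
#' @param protocol a [pf_protocol()].
#' @export
stim_offset <- function(protocol) protocol$stim_onset + stim_duration(protocol)

#' Catalog of the study's standard stimulation protocols
#'
#' Six persistent-firing protocols (three 2 s steps at 100/150/200 pA and
#' three 20 Hz pulse-train variants), the ADP/plateau protocol (250 ms train,
#' held 10 mV below spontaneous firing threshold so firing is precluded), and
#' the postburst-AHP burst (15 pulses of 2 ms, 2 nA at 50 Hz, held at -69 mV,
#' five repeats). Stimulus onsets are placed so 2 s stimuli leave a 17.75 s
#' post-offset window and 250 ms stimuli an 18 s window within a 20 s sweep.
#'
#' @return named list of [pf_protocol()] objects.
#' @export
standard_protocols <- function() {
  step <- function(amp, name)
    pf_protocol("step", step_amplitude = amp, step_duration = 2,
                holding_offset = 2, stim_onset = 0.25, name = name)
  list(
    step100 = step(100, "step100"),
    step150 = step(150, "step150"),
    step200 = step(200, "step200"),
    train20hz_2s = pf_protocol("pulse_train", train_duration = 2,
                               pulse_frequency = 20, holding_offset = 2,
                               stim_onset = 0.25, name = "train20hz_2s"),
    train20hz_250ms_2mv = pf_protocol("pulse_train", train_duration = 0.25,
                                      pulse_frequency = 20, holding_offset = 2,
                                      stim_onset = 1.75,
                                      name = "train20hz_250ms_2mv"),
    train20hz_250ms_5mv = pf_protocol("pulse_train", train_duration = 0.25,
                                      pulse_frequency = 20, holding_offset = 5,
                                      stim_onset = 1.75,
                                      name = "train20hz_250ms_5mv"),
    adp_250ms_10mv = pf_protocol("pulse_train", train_duration = 0.25,
                                 pulse_frequency = 20, holding_offset = 10,
                                 stim_onset = 1.75, name = "adp_250ms_10mv"),
    ahp_burst50hz = pf_protocol("ahp_burst", train_duration = 0.3,
                                pulse_frequency = 50, holding_offset = 0,
                                absolute_holding = -69, stim_onset = 0.25,
                                n_repeats = 5, name = "ahp_burst50hz")
  )
}

#' Idealized command-current waveform for a protocol
#'
#' Reconstructs the injected current as sampled values in pA (pulse currents
#' given in nA are stored as pA, e.g. 2 nA pulses become 2000 pA). Used by the
#' synthetic generator and by the ABF adapter when a file lacks a recorded
#' command channel.
#'
#' @param protocol a [pf_protocol()].
#' @param sample_rate sampling rate in Hz.
#' @param duration sweep duration in seconds.
#' @return numeric vector of length `round(sample_rate * duration)`, pA.
#' @export
command_waveform <- function(protocol, sample_rate, duration) {
  n <- round(sample_rate * duration)
  assert_that(stim_offset(protocol) < duration, "pf_bad_protocol",
              "stimulus extends past sweep end (%.3f s >= %.3f s)",
              stim_offset(protocol), duration)
  cur <- numeric(n)
  t <- (seq_len(n) - 1L) / sample_rate
  if (protocol$kind == "step") {
    on <- t >= protocol$stim_onset & t < stim_offset(protocol)
    cur[on] <- protocol$step_amplitude
  } else {
    starts <- pulse_times(protocol)
    w <- protocol$pulse_width_ms / 1000
    for (s in starts) cur[t >= s & t < s + w] <- protocol$pulse_amplitude_nA * 1000
  }
  cur
}

#' Pulse onset times of a pulse-train protocol, seconds from sweep start
#' @param protocol a [pf_protocol()] of kind `pulse_train` or `ahp_burst`.
#' @export
pulse_times <- function(protocol) {
  assert_that(protocol$kind != "step", "pf_bad_protocol",
              "step protocols have no pulse train")
  n_pulses <- max(1L, floor(protocol$train_duration * protocol$pulse_frequency))
  protocol$stim_onset + (seq_len(n_pulses) - 1L) / protocol$pulse_frequency
}

#' @export
print.pf_protocol <- function(x, ...) {
  cat(sprintf("<pf_protocol %s> kind=%s onset=%.3fs offset=%.3fs\n",
              x$name, x$kind, x$stim_onset, stim_offset(x)))
  invisible(x)
}
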