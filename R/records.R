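#' One episodic current-clamp sweep
#'
#' Voltage (mV) and optionally the command current (pA) sampled on a common
#' grid, together with the protocol that evoked the sweep. Time is implicit:
#' sample i sits at `(i - 1) / sample_rate` seconds from sweep start.
#'
#' @param voltage numeric vector, mV.
#' @param sample_rate sampling rate, Hz.
#' @param protocol a [pf_protocol()].
#' @param sweep_index 1-based repeat index within the protocol.
#' @param current optional command current, pA, same length as `voltage`.
#' @param duration sweep length in seconds; defaults to
#'   `length(voltage) / sample_rate`.
#' @return object of class `pf_sweep`.
#' @export
pf_sweep <- function(voltage, sample_rate, protocol, sweep_index = 1L,
                     current = NULL, duration = length(voltage) / sample_rate) {
  assert_that(is.numeric(voltage) && length(voltage) > 1,
              "pf_bad_sweep", "voltage must be a numeric series")
  assert_that(length(voltage) == round(sample_rate * duration),
              "pf_length_mismatch",
              "voltage has %d samples but sample_rate * duration = %d",
              length(voltage), round(sample_rate * duration))
  if (!is.null(current))
    assert_that(length(current) == length(voltage), "pf_length_mismatch",
                "current and voltage lengths differ (%d vs %d)",
                length(current), length(voltage))
  structure(list(voltage = as.numeric(voltage), current = current,
                 sample_rate = sample_rate, protocol = protocol,
                 sweep_index = as.integer(sweep_index), duration = duration),
            class = "pf_sweep")
}

#' Time axis of a sweep, seconds from sweep start
#' @param sweep a [pf_sweep()].
#' @export
sweep_time <- function(sweep) (seq_along(sweep$voltage) - 1L) / sweep$sample_rate

#' @export
print.pf_sweep <- function(x, ...) {
  cat(sprintf("<pf_sweep #%d> %.1f s @ %g Hz, protocol %s\n",
              x$sweep_index, x$duration, x$sample_rate, x$protocol$name))
  invisible(x)
}

#' One recorded cell with its sweeps grouped by protocol
#'
#' @param cell_id identifier string.
#' @param group behavioral group label: YN, AN, YC, YP, AU, AI or other.
#' @param spontaneous_threshold the cell's spontaneous firing threshold, mV;
#'   must exceed the resting potential.
#' @param resting_potential resting membrane potential, mV.
#' @param sweeps named list (by protocol name) of lists of [pf_sweep()].
#' @param condition recording condition label.
#' @param input_resistance input resistance in megaohm (for QC).
#' @param max_ap_height maximal AP height above holding, mV (for QC).
#' @return object of class `pf_cell`.
#' @export
pf_cell <- function(cell_id, group, spontaneous_threshold, resting_potential,
                    sweeps = list(),
                    condition = c("carbachol", "baseline",
                                  "carbachol_plus_blocker"),
                    input_resistance = NA_real_, max_ap_height = NA_real_) {
  condition <- match.arg(condition)
  assert_that(group %in% c("YN", "AN", "YC", "YP", "AU", "AI", "other"),
              "pf_bad_cell", "unknown group label '%s'", group)
  assert_that(spontaneous_threshold > resting_potential, "pf_bad_cell",
              "spontaneous threshold (%.1f) must exceed resting potential (%.1f)",
              spontaneous_threshold, resting_potential)
  structure(list(cell_id = cell_id, group = group,
                 spontaneous_threshold = spontaneous_threshold,
                 resting_potential = resting_potential, sweeps = sweeps,
                 condition = condition, input_resistance = input_resistance,
                 max_ap_height = max_ap_height),
            class = "pf_cell")
}

#' @export
print.pf_cell <- function(x, ...) {
  cat(sprintf("<pf_cell %s> group=%s threshold=%.1f mV, %d protocol(s)\n",
              x$cell_id, x$group, x$spontaneous_threshold, length(x$sweeps)))
  invisible(x)
}

#' Inclusion quality control for a recorded cell
#'
#' A cell passes iff its resting membrane potential lies in the closed
#' interval \[-80, -50\] mV, its input resistance exceeds 25 megaohm
#' (strictly), and its maximal action-potential height is at least 70 mV
#' above the holding potential. The boundary conventions follow the stated
#' inclusion criteria literally.
#'
#' @param resting_potential mV.
#' @param input_resistance megaohm.
#' @param max_ap_height_above_holding mV.
#' @return object of class `pf_cell_qc` with a logical `passes` field.
#' @export
cell_qc <- function(resting_potential, input_resistance,
                    max_ap_height_above_holding) {
  passes <- resting_potential >= -80 && resting_potential <= -50 &&
    input_resistance > 25 && max_ap_height_above_holding >= 70
  structure(list(resting_potential = resting_potential,
                 input_resistance = input_resistance,
                 max_ap_height_above_holding = max_ap_height_above_holding,
                 passes = passes),
            class = "pf_cell_qc")
}

#' One rectified-EMG trial of a trace eyeblink conditioning session
#'
#' For paired and CS-alone trials the US reference time is derived from the
#' CS timing (`cs_onset + cs_duration + trace_duration`); for US-alone trials
#' `us_onset` must be supplied.
#'
#' @param emg rectified EMG series (arbitrary units).
#' @param sample_rate Hz.
#' @param cs_onset CS onset, seconds from trial start.
#' @param cs_duration CS length, seconds (study value 0.250).
#' @param trace_duration stimulus-free trace interval, seconds (study 0.500).
#' @param trial_type `"paired"`, `"cs_alone"` or `"us_alone"`.
#' @param us_onset US onset, seconds; derived when NULL for paired/cs_alone.
#' @return object of class `pf_emg_trial`.
#' @export
pf_emg_trial <- function(emg, sample_rate, cs_onset, cs_duration = 0.25,
                         trace_duration = 0.5,
                         trial_type = c("paired", "cs_alone", "us_alone"),
                         us_onset = NULL) {
  trial_type <- match.arg(trial_type)
  if (trial_type %in% c("paired", "cs_alone")) {
    derived <- cs_onset + cs_duration + trace_duration
    if (is.null(us_onset)) us_onset <- derived
    assert_that(abs(us_onset - derived) < 1e-9, "pf_bad_trial",
                "us_onset (%.3f) must equal cs_onset + cs_duration + trace_duration (%.3f)",
                us_onset, derived)
  } else {
    assert_that(!is.null(us_onset), "pf_bad_trial",
                "us_alone trials need an explicit us_onset")
  }
  structure(list(emg = as.numeric(emg), sample_rate = sample_rate,
                 cs_onset = cs_onset, cs_duration = cs_duration,
                 trace_duration = trace_duration, us_onset = us_onset,
                 trial_type = trial_type),
            class = "pf_emg_trial")
}

#' One behavioral session (habituation = 0, training 1..5)
#'
#' Conditioned sessions hold 30 paired trials; pseudoconditioned sessions
#' hold 30 CS-alone trials pseudo-randomly interleaved with 30 US-alone
#' trials. Set `validate = FALSE` to build partial sessions (e.g. truncated
#' recordings).
#'
#' @param session_index integer, 0 for habituation.
#' @param trials list of [pf_emg_trial()].
#' @param paradigm `"conditioned"` or `"pseudoconditioned"`.
#' @param validate enforce the trial-composition invariant.
#' @return object of class `pf_session`.
#' @export
pf_session <- function(session_index, trials,
                       paradigm = c("conditioned", "pseudoconditioned"),
                       validate = TRUE) {
  paradigm <- match.arg(paradigm)
  types <- vapply(trials, function(tr) tr$trial_type, character(1))
  if (validate) {
    if (paradigm == "conditioned")
      assert_that(length(trials) == 30 && all(types == "paired"),
                  "pf_bad_session",
                  "conditioned sessions must hold 30 paired trials")
    else
      assert_that(sum(types == "cs_alone") == 30 &&
                    sum(types == "us_alone") == 30,
                  "pf_bad_session",
                  "pseudoconditioned sessions must hold 30 cs_alone + 30 us_alone trials")
  }
  structure(list(session_index = as.integer(session_index), trials = trials,
                 paradigm = paradigm),
            class = "pf_session")
}

#' One behavioral animal: a group label plus its sessions
#' @param animal_id identifier string.
#' @param group group label.
#' @param paradigm conditioned or pseudoconditioned.
#' @param sessions list of [pf_session()].
#' @export
pf_animal <- function(animal_id, group,
                      paradigm = c("conditioned", "pseudoconditioned"),
                      sessions = list()) {
  paradigm <- match.arg(paradigm)
  structure(list(animal_id = animal_id, group = group, paradigm = paradigm,
                 sessions = sessions),
            class = "pf_animal")
}

#' A cohort: recorded cells plus behavioral animals
#' @param cells list of [pf_cell()].
#' @param animals list of [pf_animal()].
#' @param metadata free-form named list stored alongside the cohort.
#' @export
pf_cohort <- function(cells = list(), animals = list(), metadata = list()) {
  if (length(cells) && is.null(names(cells)))
    names(cells) <- vapply(cells, function(cl) cl$cell_id, character(1))
  if (length(animals) && is.null(names(animals)))
    names(animals) <- vapply(animals, function(a) a$animal_id, character(1))
  structure(list(cells = cells, animals = animals, metadata = metadata),
            class = "pf_cohort")
}

#' @export
print.pf_cohort <- function(x, ...) {
  cat(sprintf("<pf_cohort> %d cell(s), %d animal(s)\n",
              length(x$cells), length(x$animals)))
  invisible(x)
}
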