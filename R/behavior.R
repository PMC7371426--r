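#' Score one EMG trial for a conditioned response
#'
#' Baseline statistics (mean and SD of the raw rectified EMG) come from the
#' `baseline_s` window ending at CS onset. The trial is a CR iff the boxcar-
#' smoothed rectified EMG exceeds `baseline_mean + sd_threshold * baseline_sd`
#' anywhere in the scoring window, the `window_s` immediately preceding US
#' onset (responses in this late window are adaptive, anticipatory blinks;
#' earlier startle/alpha responses to the CS do not count). US-alone trials
#' are never scored. The rule is scale-free: rescaling the EMG leaves the
#' outcome unchanged.
#'
#' @param trial a [pf_emg_trial()].
#' @param sd_threshold SD multiple above baseline (study rule: 4).
#' @param baseline_s baseline window length, s.
#' @param window_s scoring window length before US onset, s (study: 0.2).
#' @param smooth_ms moving-average width, ms.
#' @return list of class `pf_trial_score`: `is_cr` (NA for us_alone),
#'   `scoreable`, `baseline_mean`, `baseline_sd`, `max_in_window`,
#'   `threshold`, `window`.
#' @section Errors: `pf_insufficient_baseline` when fewer than 2 baseline
#'   samples precede the CS.
#' @export
score_trial <- function(trial, sd_threshold = 4, baseline_s = 0.25,
                        window_s = 0.2, smooth_ms = 10) {
  if (trial$trial_type == "us_alone")
    return(structure(list(is_cr = NA, scoreable = FALSE,
                          baseline_mean = NA_real_, baseline_sd = NA_real_,
                          max_in_window = NA_real_, threshold = NA_real_,
                          window = c(NA_real_, NA_real_)),
                     class = "pf_trial_score"))
  fs <- trial$sample_rate
  t <- (seq_along(trial$emg) - 1L) / fs
  base_sel <- t >= trial$cs_onset - baseline_s & t < trial$cs_onset
  assert_that(sum(base_sel) >= 2, "pf_insufficient_baseline",
              "only %d baseline samples before CS onset", sum(base_sel))
  b_mean <- mean(trial$emg[base_sel])
  b_sd <- stats::sd(trial$emg[base_sel])
  sm <- boxcar_smooth(trial$emg, max(1L, round(smooth_ms / 1000 * fs)))
  w0 <- trial$us_onset - window_s
  win_sel <- t >= w0 & t < trial$us_onset
  mx <- max(sm[win_sel])
  thr <- b_mean + sd_threshold * b_sd
  structure(list(is_cr = mx > thr, scoreable = TRUE, baseline_mean = b_mean,
                 baseline_sd = b_sd, max_in_window = mx, threshold = thr,
                 window = c(w0, trial$us_onset)),
            class = "pf_trial_score")
}

#' Session percent conditioned responses
#'
#' 100 x CR count / scoreable trials. Paired and CS-alone trials are
#' scoreable; US-alone trials are ignored.
#'
#' @param session a [pf_session()].
#' @param ... passed to [score_trial()].
#' @return percentage in \[0, 100\].
#' @section Errors: `pf_empty_input` with zero scoreable trials.
#' @export
session_pct_cr <- function(session, ...) {
  scores <- lapply(session$trials, score_trial, ...)
  cr <- vapply(scores, function(s) s$is_cr, logical(1))
  cr <- cr[!is.na(cr)]
  assert_that(length(cr) >= 1, "pf_empty_input",
              "session has no scoreable trials")
  100 * mean(cr)
}

#' Classify an aged animal by the 60% learning criterion
#'
#' Animals that reach 60% CRs on the final training session are aged
#' unimpaired (`AU`); the criterion is inclusive at exactly 60.
#'
#' @param final_session_pct final-session %CR in \[0, 100\].
#' @return `"AU"` or `"AI"`.
#' @export
classify_aged <- function(final_session_pct) {
  assert_that(final_session_pct >= 0 && final_session_pct <= 100,
              "pf_out_of_range", "%%CR must lie in [0, 100]")
  if (final_session_pct >= 60) "AU" else "AI"
}

#' Learning curves: per-animal per-session %CR with group summaries
#'
#' Scores training sessions 1-5 (habituation session 0 is never scored) and
#' tabulates per-animal %CR plus group mean +/- SEM per session and the
#' final-session values.
#'
#' @param animals list of [pf_animal()].
#' @param ... passed to [score_trial()].
#' @return list: `per_animal` (data.table animal_id, group, session,
#'   pct_cr), `group_summary` (group, session, n, mean_pct, sem_pct),
#'   `final` (animal_id, group, final_session_pct).
#' @export
learning_curves <- function(animals, ...) {
  assert_that(length(animals) >= 1, "pf_empty_input", "no animals")
  rows <- list()
  for (an in animals) {
    for (sess in an$sessions) {
      if (sess$session_index == 0L) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        animal_id = an$animal_id, group = an$group,
        session = sess$session_index,
        pct_cr = session_pct_cr(sess, ...))
    }
  }
  per_animal <- data.table::rbindlist(rows)
  data.table::setorder(per_animal, group, animal_id, session)
  pct_cr <- session <- NULL  # NSE bindings
  group_summary <- per_animal[, list(
    n = .N, mean_pct = mean(pct_cr),
    sem_pct = stats::sd(pct_cr) / sqrt(.N)), by = c("group", "session")]
  final <- per_animal[, list(final_session_pct = pct_cr[which.max(session)]),
                      by = c("animal_id", "group")]
  list(per_animal = per_animal, group_summary = group_summary,
       final = final)
}
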