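half_sine_burst <- function(t, center, width, amplitude) {
  rel <- t - (center - width / 2)
  inside <- rel > 0 & rel < width
  out <- numeric(length(t))
  out[inside] <- amplitude * sin(pi * rel[inside] / width)
  out
}

#' Construct one synthetic rectified-EMG trial
#'
#' Baseline is rectified white noise (`abs` of Gaussian with sd `noise_sd`).
#' A conditioned response, when present, is a half-sine burst of width
#' `burst_width` s and amplitude `burst_sd * noise_sd` centered at
#' `burst_center` (default: drawn uniformly inside the 200 ms scoring window
#' preceding the US reference time). Non-CR trials optionally carry an
#' "alpha" deflection just after CS onset, outside the scoring window, and
#' paired / US-alone trials carry an unconditioned-response burst after US
#' onset.
#'
#' @param is_cr logical: place a CR burst.
#' @param trial_type `"paired"`, `"cs_alone"` or `"us_alone"`.
#' @param sample_rate Hz.
#' @param cs_onset CS onset, s.
#' @param duration trial length, s.
#' @param noise_sd baseline noise sd (EMG units).
#' @param burst_sd CR burst amplitude in units of `noise_sd`.
#' @param burst_width CR burst width, s.
#' @param burst_center optional fixed CR burst center, s.
#' @param alpha add an alpha deflection (non-CR trials).
#' @return a [pf_emg_trial()].
#' @export
synth_emg_trial <- function(is_cr, trial_type = "paired", sample_rate = 1000,
                            cs_onset = 0.5, duration = 1.7, noise_sd = 1,
                            burst_sd = 6, burst_width = 0.05,
                            burst_center = NULL, alpha = FALSE) {
  n <- round(sample_rate * duration)
  t <- (seq_len(n) - 1L) / sample_rate
  us_onset <- cs_onset + 0.75
  emg <- abs(stats::rnorm(n, 0, noise_sd))
  if (trial_type != "us_alone" && is_cr) {
    if (is.null(burst_center))
      burst_center <- stats::runif(1, us_onset - 0.15, us_onset - 0.05)
    emg <- emg + half_sine_burst(t, burst_center, burst_width,
                                 burst_sd * noise_sd)
  }
  if (alpha && !is_cr && trial_type != "us_alone")
    emg <- emg + half_sine_burst(t, cs_onset + 0.05, burst_width,
                                 burst_sd * noise_sd)
  if (trial_type %in% c("paired", "us_alone"))
    emg <- emg + half_sine_burst(t, us_onset + 0.05, 0.08, 8 * noise_sd)
  pf_emg_trial(emg, sample_rate, cs_onset = cs_onset,
               trial_type = trial_type,
               us_onset = if (trial_type == "us_alone") us_onset else NULL)
}

#' Generate a synthetic behavioral cohort with ground truth
#'
#' Per animal: five training sessions of 30 trials (plus an unscored
#' habituation session when `include_habituation`). Conditioned animals get
#' paired trials whose CR probability follows the group's
#' `cr_prob_by_session`; pseudoconditioned animals (group label `YP`, or any
#' spec passed through `paradigm_by_group`) get 30 CS-alone trials
#' pseudo-randomly interleaved with 30 US-alone trials. A CR trial contains a
#' burst exceeding the 4-SD scoring criterion inside the 200 ms pre-US
#' window; non-CR trials are baseline noise, optionally with an early alpha
#' deflection outside the window. With `exact_counts = TRUE` the per-session
#' CR count is `round(30 * p)` deterministically instead of binomial.
#'
#' @param specs list of [group_spec()] (uses `n_animals` and
#'   `cr_prob_by_session`).
#' @param seed integer RNG seed.
#' @param noise_sd,burst_sd,alpha_prob trial construction parameters.
#' @param sample_rate Hz.
#' @param include_habituation store a session 0 of stimulus-free trials.
#' @param exact_counts deterministic CR counts per session.
#' @return list with `animals` (list of [pf_animal()]) and `truth`
#'   (data.table of per-trial intended CR flags).
#' @export
generate_behavior_cohort <- function(specs, seed, noise_sd = 1, burst_sd = 6,
                                     alpha_prob = 0.3, sample_rate = 1000,
                                     include_habituation = FALSE,
                                     exact_counts = FALSE) {
  if (inherits(specs, "pf_group_spec")) specs <- list(specs)
  set.seed(as.integer(seed))
  animals <- list()
  truth <- list()
  for (spec in specs) {
    paradigm <- if (identical(spec$group, "YP")) "pseudoconditioned"
                else "conditioned"
    for (ai in seq_len(spec$n_animals)) {
      animal_id <- sprintf("%s_a%03d", spec$group, ai)
      sessions <- list()
      if (include_habituation) {
        hab <- lapply(1:30, function(j)
          synth_emg_trial(FALSE, "cs_alone", sample_rate,
                          noise_sd = noise_sd, burst_sd = burst_sd))
        sessions[[length(sessions) + 1L]] <-
          pf_session(0L, hab, paradigm, validate = FALSE)
      }
      for (s in 1:5) {
        p <- spec$cr_prob_by_session[s]
        if (paradigm == "conditioned") {
          cr <- if (exact_counts) {
            flags <- rep(FALSE, 30)
            flags[seq_len(round(30 * p))] <- TRUE
            flags
          } else stats::runif(30) < p
          alpha <- stats::runif(30) < alpha_prob
          trials <- lapply(1:30, function(j)
            synth_emg_trial(cr[j], "paired", sample_rate,
                            noise_sd = noise_sd, burst_sd = burst_sd,
                            alpha = alpha[j]))
          types <- rep("paired", 30)
        } else {
          cr_cs <- if (exact_counts) {
            flags <- rep(FALSE, 30)
            flags[seq_len(round(30 * p))] <- TRUE
            flags
          } else stats::runif(30) < p
          cs_trials <- lapply(1:30, function(j)
            synth_emg_trial(cr_cs[j], "cs_alone", sample_rate,
                            noise_sd = noise_sd, burst_sd = burst_sd,
                            alpha = stats::runif(1) < alpha_prob))
          us_trials <- lapply(1:30, function(j)
            synth_emg_trial(FALSE, "us_alone", sample_rate,
                            noise_sd = noise_sd, burst_sd = burst_sd))
          ord <- sample(60)
          trials <- c(cs_trials, us_trials)[ord]
          cr <- c(cr_cs, rep(FALSE, 30))[ord]
          types <- c(rep("cs_alone", 30), rep("us_alone", 30))[ord]
        }
        sessions[[length(sessions) + 1L]] <-
          pf_session(s, trials, paradigm)
        truth[[length(truth) + 1L]] <- data.table::data.table(
          animal_id = animal_id, group = spec$group, session_index = s,
          trial = seq_along(trials), trial_type = types, is_cr = cr)
      }
      animals[[animal_id]] <- pf_animal(animal_id, spec$group, paradigm,
                                        sessions)
    }
  }
  list(animals = animals, truth = data.table::rbindlist(truth))
}
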