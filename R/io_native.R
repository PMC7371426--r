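# Native on-disk cohort format
#
# dir/
#   cohort.json                      manifest (format_version, cell/animal ids)
#   cells/<id>/cell.json             per-cell metadata incl. protocol defs
#   cells/<id>/sweeps/<prot>_<k>.csv time_s, voltage_mV, current_pA
#   animals/<id>/animal.json         per-animal metadata incl. trial timing
#   animals/<id>/sessions/s<k>/trial_<j>.csv   time_s, emg
#
# JSON metadata round-trips bit-exactly; series round-trip to the precision
# declared in the manifest (float_digits significant digits).

PF_FORMAT_VERSION <- "1.0"
PF_FLOAT_DIGITS <- 9L

pf_write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
}

pf_read_json <- function(path) {
  assert_that(file.exists(path), "pf_missing_metadata",
              "metadata file missing: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

need_key <- function(meta, keys, path) {
  missing <- setdiff(keys, names(meta))
  assert_that(length(missing) == 0, "pf_missing_metadata",
              "metadata %s lacks key(s): %s", path,
              paste(missing, collapse = ", "))
}

proto_to_meta <- function(p) unclass(p)

proto_from_meta <- function(m, path) {
  need_key(m, c("kind", "stim_onset"), path)
  pf_protocol(kind = m$kind,
              step_amplitude = m$step_amplitude %||% NA_real_,
              step_duration = m$step_duration %||% NA_real_,
              pulse_amplitude_nA = m$pulse_amplitude_nA %||% 2,
              pulse_width_ms = m$pulse_width_ms %||% 2,
              pulse_frequency = m$pulse_frequency %||% 20,
              train_duration = m$train_duration %||% NA_real_,
              holding_offset = m$holding_offset %||% 0,
              absolute_holding = m$absolute_holding %||% NA_real_,
              stim_onset = m$stim_onset,
              n_repeats = m$n_repeats %||% 3,
              name = m$name)
}

#' Write a cohort to a native-format directory
#'
#' @param cohort a [pf_cohort()].
#' @param dir target directory (created if needed; must be empty or absent).
#' @return `dir`, invisibly.
#' @seealso [read_native_cohort()]
#' @export
write_native_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "pf_cohort"), "pf_bad_cohort",
              "cohort must be a pf_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pf_write_json(list(format_version = PF_FORMAT_VERSION,
                     float_digits = PF_FLOAT_DIGITS,
                     cells = as.list(names(cohort$cells)),
                     animals = as.list(names(cohort$animals)),
                     metadata = cohort$metadata),
                file.path(dir, "cohort.json"))
  for (cell in cohort$cells) write_native_cell(cell, dir)
  for (animal in cohort$animals) write_native_animal(animal, dir)
  invisible(dir)
}

write_native_cell <- function(cell, dir) {
  cdir <- file.path(dir, "cells", cell$cell_id)
  sdir <- file.path(cdir, "sweeps")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  protocols <- list()
  for (pname in names(cell$sweeps)) {
    sweeps <- cell$sweeps[[pname]]
    entries <- vector("list", length(sweeps))
    for (i in seq_along(sweeps)) {
      sw <- sweeps[[i]]
      fname <- sprintf("%s_%02d.csv", pname, sw$sweep_index)
      dt <- data.table::data.table(
        time_s = signif(sweep_time(sw), PF_FLOAT_DIGITS),
        voltage_mV = signif(sw$voltage, PF_FLOAT_DIGITS))
      if (!is.null(sw$current))
        dt[, "current_pA" := signif(sw$current, PF_FLOAT_DIGITS)]
      data.table::fwrite(dt, file.path(sdir, fname))
      entries[[i]] <- list(file = fname, sweep_index = sw$sweep_index,
                           sample_rate = sw$sample_rate,
                           duration = sw$duration,
                           n_samples = length(sw$voltage),
                           has_current = !is.null(sw$current))
    }
    protocols[[pname]] <- list(protocol = proto_to_meta(sweeps[[1]]$protocol),
                               sweeps = entries)
  }
  pf_write_json(list(format_version = PF_FORMAT_VERSION,
                     cell_id = cell$cell_id, group = cell$group,
                     spontaneous_threshold = cell$spontaneous_threshold,
                     resting_potential = cell$resting_potential,
                     condition = cell$condition,
                     input_resistance = cell$input_resistance,
                     max_ap_height = cell$max_ap_height,
                     protocols = protocols),
                file.path(cdir, "cell.json"))
}

write_native_animal <- function(animal, dir) {
  adir <- file.path(dir, "animals", animal$animal_id)
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  sess_meta <- list()
  for (sess in animal$sessions) {
    skey <- sprintf("s%d", sess$session_index)
    tdir <- file.path(adir, "sessions", skey)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    trials <- vector("list", length(sess$trials))
    for (j in seq_along(sess$trials)) {
      tr <- sess$trials[[j]]
      fname <- sprintf("trial_%03d.csv", j)
      data.table::fwrite(data.table::data.table(
        time_s = signif((seq_along(tr$emg) - 1L) / tr$sample_rate,
                        PF_FLOAT_DIGITS),
        emg = signif(tr$emg, PF_FLOAT_DIGITS)), file.path(tdir, fname))
      trials[[j]] <- list(file = fname, sample_rate = tr$sample_rate,
                          cs_onset = tr$cs_onset, cs_duration = tr$cs_duration,
                          trace_duration = tr$trace_duration,
                          us_onset = tr$us_onset, trial_type = tr$trial_type,
                          n_samples = length(tr$emg))
    }
    sess_meta[[skey]] <- list(session_index = sess$session_index,
                              paradigm = sess$paradigm, trials = trials)
  }
  pf_write_json(list(format_version = PF_FORMAT_VERSION,
                     animal_id = animal$animal_id, group = animal$group,
                     paradigm = animal$paradigm, sessions = sess_meta),
                file.path(adir, "animal.json"))
}

read_series_csv <- function(path, expected_rows, cols) {
  assert_that(file.exists(path), "pf_missing_metadata",
              "series file missing: %s", path)
  dt <- data.table::fread(path)
  need_key(dt, cols, path)
  assert_that(nrow(dt) == expected_rows, "pf_length_mismatch",
              "%s has %d rows but metadata declares %d",
              path, nrow(dt), expected_rows)
  assert_that(all(diff(dt$time_s) > 0), "pf_nonmonotonic_time",
              "%s: time_s is not strictly increasing", path)
  dt
}

#' Read a native-format cohort directory
#'
#' Inverse of [write_native_cohort()]. Raises named conditions on malformed
#' input: `pf_missing_metadata` (absent files or JSON keys),
#' `pf_length_mismatch` (series shorter/longer than declared) and
#' `pf_nonmonotonic_time` (non-increasing time column).
#'
#' @param dir a directory written by [write_native_cohort()].
#' @return a [pf_cohort()].
#' @export
read_native_cohort <- function(dir) {
  manifest <- pf_read_json(file.path(dir, "cohort.json"))
  need_key(manifest, c("format_version", "cells", "animals"),
           file.path(dir, "cohort.json"))
  cells <- lapply(unlist(manifest$cells), function(id)
    read_native_cell(file.path(dir, "cells", id)))
  animals <- lapply(unlist(manifest$animals), function(id)
    read_native_animal(file.path(dir, "animals", id)))
  meta <- manifest$metadata
  if (length(meta) == 0) meta <- list()
  pf_cohort(cells = cells, animals = animals, metadata = meta)
}

read_native_cell <- function(cdir) {
  path <- file.path(cdir, "cell.json")
  meta <- pf_read_json(path)
  need_key(meta, c("cell_id", "group", "spontaneous_threshold",
                   "resting_potential", "condition", "protocols"), path)
  sweeps <- list()
  for (pname in names(meta$protocols)) {
    pm <- meta$protocols[[pname]]
    proto <- proto_from_meta(pm$protocol, path)
    entries <- pm$sweeps
    if (is.data.frame(entries))
      entries <- split(entries, seq_len(nrow(entries)))
    entries <- unname(entries)
    sweeps[[pname]] <- lapply(entries, function(e) {
      fp <- file.path(cdir, "sweeps", e$file)
      cols <- c("time_s", "voltage_mV")
      if (isTRUE(e$has_current)) cols <- c(cols, "current_pA")
      dt <- read_series_csv(fp, e$n_samples, cols)
      pf_sweep(dt$voltage_mV, sample_rate = e$sample_rate, protocol = proto,
               sweep_index = e$sweep_index,
               current = if (isTRUE(e$has_current)) dt$current_pA else NULL,
               duration = e$duration)
    })
  }
  pf_cell(meta$cell_id, meta$group, meta$spontaneous_threshold,
          meta$resting_potential, sweeps = sweeps, condition = meta$condition,
          input_resistance = meta$input_resistance %||% NA_real_,
          max_ap_height = meta$max_ap_height %||% NA_real_)
}

read_native_animal <- function(adir) {
  path <- file.path(adir, "animal.json")
  meta <- pf_read_json(path)
  need_key(meta, c("animal_id", "group", "paradigm", "sessions"), path)
  sessions <- lapply(meta$sessions, function(sm) {
    entries <- sm$trials
    if (is.data.frame(entries))
      entries <- split(entries, seq_len(nrow(entries)))
    entries <- unname(entries)
    trials <- lapply(seq_along(entries), function(j) {
      e <- entries[[j]]
      fp <- file.path(adir, "sessions", sprintf("s%d", sm$session_index),
                      e$file)
      dt <- read_series_csv(fp, e$n_samples, c("time_s", "emg"))
      pf_emg_trial(dt$emg, sample_rate = e$sample_rate,
                   cs_onset = e$cs_onset, cs_duration = e$cs_duration,
                   trace_duration = e$trace_duration,
                   trial_type = e$trial_type, us_onset = e$us_onset)
    })
    pf_session(sm$session_index, trials, paradigm = sm$paradigm,
               validate = FALSE)
  })
  names(sessions) <- NULL
  pf_animal(meta$animal_id, meta$group, meta$paradigm, sessions)
}
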