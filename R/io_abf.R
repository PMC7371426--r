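# Read-only adapter for Axon Binary Format v1 (pre-2.0) episodic files.
#
# Only the fields the pipeline needs are parsed, at their fixed ABF1 header
# offsets (little-endian, 2048-byte header, data section addressed in
# 512-byte blocks). ABF2 files and non-episodic layouts raise named errors;
# the rest of the package has no dependency on this adapter.

abf1_read_header <- function(con) {
  seek_read <- function(offset, what, n, size = NA) {
    seek(con, offset)
    readBin(con, what, n = n, size = size, endian = "little")
  }
  sig <- rawToChar(seek_read(0, "raw", 4))
  h <- list(signature = sig)
  h$version <- seek_read(4, "double", 1, size = 4)
  h$operation_mode <- seek_read(8, "integer", 1, size = 2)
  h$actual_acq_length <- seek_read(10, "integer", 1, size = 4)
  h$actual_episodes <- seek_read(16, "integer", 1, size = 4)
  h$data_section_ptr <- seek_read(40, "integer", 1, size = 4)
  h$data_format <- seek_read(100, "integer", 1, size = 2)
  h$n_channels <- seek_read(120, "integer", 1, size = 2)
  h$sample_interval_us <- seek_read(122, "double", 1, size = 4)
  h$samples_per_episode <- seek_read(138, "integer", 1, size = 4)
  h$adc_range <- seek_read(244, "double", 1, size = 4)
  h$adc_resolution <- seek_read(252, "integer", 1, size = 4)
  raw_names <- seek_read(442, "raw", 160)
  h$channel_names <- vapply(seq_len(16), function(i) {
    trimws(rawToChar(raw_names[((i - 1) * 10 + 1):(i * 10)]))
  }, character(1))
  raw_units <- seek_read(602, "raw", 128)
  h$channel_units <- vapply(seq_len(16), function(i) {
    trimws(rawToChar(raw_units[((i - 1) * 8 + 1):(i * 8)]))
  }, character(1))
  h$programmable_gain <- seek_read(730, "double", 16, size = 4)
  h$instrument_scale <- seek_read(922, "double", 16, size = 4)
  h$instrument_offset <- seek_read(986, "double", 16, size = 4)
  h$signal_gain <- seek_read(1050, "double", 16, size = 4)
  h$signal_offset <- seek_read(1114, "double", 16, size = 4)
  h
}

abf_resolve_channel <- function(h, key) {
  if (is.null(key)) return(NA_integer_)
  active <- h$channel_names[seq_len(h$n_channels)]
  if (is.character(key)) {
    idx <- match(key, active)
    assert_that(!is.na(idx), "pf_abf_missing_channel",
                "channel '%s' not in file (channels: %s)", key,
                paste(active, collapse = ", "))
  } else {
    idx <- as.integer(key)
    assert_that(idx >= 1 && idx <= h$n_channels, "pf_abf_missing_channel",
                "channel index %d out of range (file has %d channels)",
                idx, h$n_channels)
  }
  idx
}

#' Read episodic sweeps from an Axon Binary Format v1 file
#'
#' Parses an ABF 1.x episodic ("waveform fixed-length") recording and returns
#' one [pf_sweep()] per episode, with voltage in mV and command current in pA
#' (nA channels are rescaled). When the file has no recorded command channel,
#' supply `protocol` and the command waveform is reconstructed from the
#' protocol definition via [command_waveform()].
#'
#' @param path ABF file path.
#' @param channel_map list with elements `voltage` (required) and `current`
#'   (optional): channel names as recorded in the file, or 1-based indices.
#' @param protocol optional [pf_protocol()] attached to the sweeps (required
#'   when `current` is absent and a command trace is wanted).
#' @return list of [pf_sweep()].
#' @section Errors: `pf_abf_unsupported_version` for ABF2 or unrecognized
#'   files, `pf_abf_unsupported_layout` for non-episodic (e.g. gap-free)
#'   recordings, `pf_abf_missing_channel` for unresolvable channels.
#' @export
read_abf_sweep <- function(path, channel_map = list(voltage = 1L),
                           protocol = NULL) {
  assert_that(file.exists(path), "pf_missing_metadata",
              "ABF file missing: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- abf1_read_header(con)
  assert_that(identical(substr(h$signature, 1, 3), "ABF") &&
                h$version < 2.0, "pf_abf_unsupported_version",
              "not an ABF1 file (signature '%s', version %.2f)",
              h$signature, h$version)
  assert_that(h$operation_mode == 5L, "pf_abf_unsupported_layout",
              "only episodic (waveform) ABF recordings are supported; operation mode %d",
              h$operation_mode)
  v_idx <- abf_resolve_channel(h, channel_map$voltage)
  c_idx <- abf_resolve_channel(h, channel_map$current)
  assert_that(!is.na(v_idx), "pf_abf_missing_channel",
              "channel_map$voltage is required")

  seek(con, h$data_section_ptr * 512)
  n_total <- h$actual_acq_length
  if (h$data_format == 0L) {
    raw_data <- readBin(con, "integer", n = n_total, size = 2,
                        endian = "little")
  } else {
    raw_data <- readBin(con, "double", n = n_total, size = 4,
                        endian = "little")
  }
  nch <- h$n_channels
  sample_rate <- 1e6 / (h$sample_interval_us * nch)
  samples_per_ep <- h$samples_per_episode            # total over channels
  per_chan <- samples_per_ep %/% nch
  n_ep <- h$actual_episodes

  scale_chan <- function(idx, x) {
    if (h$data_format != 0L) return(x)
    x * h$adc_range / (h$adc_resolution * h$instrument_scale[idx] *
                         h$programmable_gain[idx] * h$signal_gain[idx]) +
      h$instrument_offset[idx] - h$signal_offset[idx]
  }
  unit_factor <- function(idx, kind) {
    u <- h$channel_units[idx]
    if (kind == "current" && identical(u, "nA")) 1000 else 1
  }

  lapply(seq_len(n_ep), function(ep) {
    off <- (ep - 1L) * samples_per_ep
    block <- raw_data[(off + 1L):(off + samples_per_ep)]
    chan <- function(idx) block[seq(idx, samples_per_ep, by = nch)]
    voltage <- scale_chan(v_idx, chan(v_idx)) * unit_factor(v_idx, "voltage")
    duration <- per_chan / sample_rate
    current <- if (!is.na(c_idx)) {
      scale_chan(c_idx, chan(c_idx)) * unit_factor(c_idx, "current")
    } else if (!is.null(protocol)) {
      command_waveform(protocol, sample_rate, duration)
    }
    pf_sweep(voltage, sample_rate = sample_rate,
             protocol = protocol %||% pf_protocol(
               "step", step_amplitude = 0, step_duration = duration / 2,
               stim_onset = 0, name = "unknown"),
             sweep_index = ep, current = current, duration = duration)
  })
}
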