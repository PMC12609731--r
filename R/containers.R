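#' Continuous multichannel EEG recording
#'
#' Light container for a continuous recording: a channels x samples matrix of
#' microvolt values plus sampling rate and channel labels.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param rate sampling rate in Hz.
#' @param labels character vector of channel labels (unique, one per row).
#' @param subject_id,group optional identifiers carried through the pipeline.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, labels,
                          subject_id = NA_character_, group = NA_character_) {
  stopifnot(is.matrix(data), nrow(data) == length(labels), rate > 0)
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  structure(list(data = data, rate = rate, labels = as.character(labels),
                 subject_id = subject_id, group = group),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Epoched EEG recording
#'
#' Per-subject stack of trials, cut around the swallowing cue. The time axis
#' is milliseconds relative to the cue and spans `[-1000, 5000)` by default
#' (half-open so every trial has the same number of samples).
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param rate sampling rate in Hz.
#' @param labels channel labels; must contain C3, Cz and C4.
#' @param t_start_ms time of the first sample relative to the cue (ms).
#' @param subject_id,group identifiers.
#' @return object of class `eeg_epochs` with a `time_ms` axis.
#' @export
eeg_epochs <- function(data, rate, labels, t_start_ms = -1000,
                       subject_id = NA_character_, group = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            dim(data)[2] == length(labels), rate > 0)
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(c("C3", "Cz", "C4") %in% labels))
    stop("epoched recordings must contain channels C3, Cz and C4")
  n <- dim(data)[3]
  structure(list(data = data, rate = rate, labels = as.character(labels),
                 time_ms = t_start_ms + (seq_len(n) - 1) * 1000 / rate,
                 subject_id = subject_id, group = group,
                 n_valid_trials = dim(data)[1]),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> subject %s (%s): %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] ms\n",
    x$subject_id, x$group, d[1], d[2], d[3], x$rate,
    min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Time-frequency (ERSP) map for one channel
#'
#' `values` is a time x frequency matrix; `valid` marks cells whose wavelet
#' support lies fully inside the epoch (edge cells are masked, not
#' zero-filled). `stage` tracks the processing state:
#' `raw_power` (per-trial linear power, uV^2), `trial_normalized` (per-trial,
#' divided by the full-epoch mean per frequency), `averaged` (trial mean,
#' linear ratio) and `db_corrected` (pre-stimulus baseline corrected,
#' 10*log10 dB; negative values indicate desynchronization).
#'
#' @param values time x frequency numeric matrix.
#' @param time_ms time axis in ms relative to the cue.
#' @param freqs frequency axis in Hz.
#' @param channel channel label.
#' @param stage processing stage, see above.
#' @param valid logical matrix like `values`; defaults to all-valid.
#' @param n_trials number of trials behind an averaged map.
#' @return object of class `tfr_map`.
#' @export
tfr_map <- function(values, time_ms, freqs, channel,
                    stage = c("raw_power", "trial_normalized",
                              "averaged", "db_corrected"),
                    valid = NULL, n_trials = NA_integer_) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values),
            nrow(values) == length(time_ms),
            ncol(values) == length(freqs))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(identical(dim(valid), dim(values)))
  structure(list(values = values, valid = valid,
                 time_ms = as.numeric(time_ms), freqs = as.numeric(freqs),
                 channel = channel, stage = stage,
                 n_trials = n_trials),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map> %s [%s]: %d times x %d freqs (%g-%g Hz)",
              x$channel, x$stage, length(x$time_ms), length(x$freqs),
              min(x$freqs), max(x$freqs)))
  if (!is.na(x$n_trials)) cat(sprintf(", %d trials", x$n_trials))
  cat("\n")
  invisible(x)
}

# shared sanity check for grid compatibility
.same_grid <- function(a, b) {
  isTRUE(all.equal(a$time_ms, b$time_ms)) &&
    isTRUE(all.equal(a$freqs, b$freqs))
}
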