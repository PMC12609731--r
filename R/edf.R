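# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# one-second data records, ASCII header. Covers continuous recordings as
# produced by this package; events travel in a CSV sidecar
# (columns onset_sample, label).

.edf_field <- function(x, width) {
  s <- substr(format(x, width = width), 1, width)
  formatC(s, width = width, flag = "-")
}

.edf_num <- function(x, width = 8) {
  s <- formatC(x, width = width, format = "g", digits = 6)
  s <- gsub(" ", "", s)
  .edf_field(s, width)
}

#' Write a continuous recording to an EDF file
#'
#' Samples are quantized to 16 bits over a per-channel symmetric physical
#' range covering the data, so the round-trip error is bounded by
#' `physical_range / 2^16` per sample. The recording duration must be a
#' whole number of seconds (EDF data records are 1 s here).
#'
#' @param recording an [eeg_recording()].
#' @param events data.frame with columns `onset_sample` (1-based) and
#'   `label`, written as a CSV sidecar `<path>.events.csv`; pass `NULL` to
#'   skip.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, events = NULL, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  if (ncol(x) == 0) stop("cannot write an empty recording")
  rate <- recording$rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  rate <- round(rate)
  n_rec <- ncol(x) / rate
  if (abs(n_rec - round(n_rec)) > 1e-9)
    stop("recording duration must be a whole number of seconds")
  n_rec <- round(n_rec)
  ns <- nrow(x)

  pmax_raw <- apply(abs(x), 1, max)
  pmax_raw[pmax_raw == 0] <- 1
  pmax_str <- vapply(pmax_raw * 1.0001, function(v)
    gsub(" ", "", formatC(v, width = 8, format = "g", digits = 6)),
    character(1))
  pmax_num <- as.numeric(pmax_str)  # quantize against the header as written
  pmax_num <- pmax(pmax_num, pmax_raw)  # header rounding must not clip

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field("synthetic swallowing-EEG", 80),
    .edf_field(paste0("Startdate 01-JAN-2000 subject ",
                      recording$subject_id), 80),
    "01.01.00", "00.00.00",
    .edf_num(256 * (ns + 1), 8),
    .edf_field("", 44),
    .edf_num(n_rec, 8),
    .edf_num(1, 8),
    .edf_num(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(recording$labels, .edf_field, character(1),
                          width = 16), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80 * ns), con, eos = NULL)                # transducer
  writeChar(strrep(.edf_field("uV", 8), ns), con, eos = NULL)     # phys dim
  writeChar(paste0(vapply(-pmax_num, .edf_num, character(1)),
                   collapse = ""), con, eos = NULL)               # phys min
  writeChar(paste0(vapply(pmax_num, .edf_num, character(1)),
                   collapse = ""), con, eos = NULL)               # phys max
  writeChar(strrep(.edf_field("-32768", 8), ns), con, eos = NULL) # dig min
  writeChar(strrep(.edf_field("32767", 8), ns), con, eos = NULL)  # dig max
  writeChar(strrep(" ", 80 * ns), con, eos = NULL)                # prefilter
  writeChar(strrep(.edf_num(rate, 8), ns), con, eos = NULL)       # spr
  writeChar(strrep(" ", 32 * ns), con, eos = NULL)                # reserved

  # re-parse header numbers so writer and reader share the exact scaling
  pmin_h <- as.numeric(vapply(-pmax_num, .edf_num, character(1)))
  pmax_h <- as.numeric(vapply(pmax_num, .edf_num, character(1)))
  for (r in seq_len(n_rec)) {
    sl <- ((r - 1) * rate + 1):(r * rate)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, sl] - pmin_h[ch]) / (pmax_h[ch] - pmin_h[ch]) *
                     65535 - 32768)
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  if (!is.null(events)) write_events(events, paste0(path, ".events.csv"))
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any 16-bit continuous EDF)
#'
#' @param path EDF file path.
#' @return list with `recording` (an [eeg_recording()]) and `events`
#'   (data.frame, or `NULL` when no sidecar exists).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  version <- trimws(rd(8))
  if (version != "0") stop("corrupt EDF header (bad version field)")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns <= 0 || is.na(n_rec)) stop("corrupt EDF header")
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- trimws(rdv(16))
  rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (256 * (ns + 1) != hdr_bytes) stop("corrupt EDF header (size mismatch)")
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  rate <- spr[1] / rec_dur
  x <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    sl <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2, endian = "little",
                     signed = TRUE)
      x[ch, sl] <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax[ch] - pmin[ch]) + pmin[ch]
    }
  }
  ev_path <- paste0(path, ".events.csv")
  events <- if (file.exists(ev_path)) read_events(ev_path) else NULL
  list(recording = eeg_recording(x, rate, labels), events = events)
}

#' Write / read an event table (CSV sidecar)
#'
#' @param events data.frame with columns `onset_sample` and `label`.
#' @param path CSV path.
#' @return `path` invisibly / the event data.frame.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset_sample", "label") %in% names(events)) ||
              nrow(events) == 0)
  if (nrow(events) == 0)
    events <- data.frame(onset_sample = integer(0), label = character(0))
  utils::write.csv(events[, c("onset_sample", "label")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(onset_sample = "integer",
                                       label = "character"))
  ev
}

#' Concatenate an epoched recording into a continuous one
#'
#' Epochs are laid end to end; the returned event table marks each trial's
#' cue sample, so [epoch_recording()] recovers the original trial stack.
#' Useful for EDF export of synthetic cohorts.
#'
#' @param epochs an [eeg_epochs()].
#' @return list with `recording` and `events`.
#' @export
flatten_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  x <- matrix(0, d[2], d[1] * d[3])
  for (tr in seq_len(d[1]))
    x[, ((tr - 1) * d[3] + 1):(tr * d[3])] <- epochs$data[tr, , ]
  cue_offset <- which.min(abs(epochs$time_ms))  # sample at t = 0
  events <- data.frame(
    onset_sample = (seq_len(d[1]) - 1L) * d[3] + as.integer(cue_offset),
    label = "swallow_cue", stringsAsFactors = FALSE)
  list(recording = eeg_recording(x, epochs$rate, epochs$labels,
                                 subject_id = epochs$subject_id,
                                 group = epochs$group),
       events = events)
}
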