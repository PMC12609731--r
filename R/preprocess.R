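# Preprocessing chain: resampling, zero-phase band-limiting, robust channel
# rejection with spatial interpolation, epoching, common average reference,
# subject-level inclusion filtering.

#' Preprocessing configuration
#'
#' @param target_rate resampling target in Hz.
#' @param hp_cutoff,lp_cutoff high-/low-pass corner frequencies (Hz) of the
#'   zero-phase 4th-order Butterworth filters (applied forward-backward,
#'   effective 8th order, no group delay).
#' @param reject_sd channel-rejection threshold: a channel is rejected when
#'   its MAD-based robust amplitude exceeds `reject_sd` times the median
#'   robust amplitude across channels.
#' @param min_valid_trials subjects with fewer valid trials are excluded.
#' @param reference only `"common_average"` is supported.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 512, hp_cutoff = 7,
                              lp_cutoff = 35, reject_sd = 10,
                              min_valid_trials = 20,
                              reference = "common_average") {
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < target_rate / 2))
    stop("need 0 < hp_cutoff < lp_cutoff < target_rate/2")
  reference <- match.arg(reference, "common_average")
  structure(list(target_rate = target_rate, hp_cutoff = hp_cutoff,
                 lp_cutoff = lp_cutoff, reject_sd = reject_sd,
                 min_valid_trials = min_valid_trials, reference = reference),
            class = "preprocess_config")
}

# apply a vector -> vector function over the sample axis of a recording or
# epoch stack; `new_rate` updates the rate (and time axis) when resampling.
.map_samples <- function(x, fun, new_rate = NULL) {
  if (inherits(x, "eeg_recording")) {
    out <- t(apply(x$data, 1, fun))
    x$data <- out
    if (!is.null(new_rate)) x$rate <- new_rate
    return(x)
  }
  if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    first <- fun(x$data[1, 1, ])
    out <- array(0, c(d[1], d[2], length(first)))
    out[1, 1, ] <- first
    for (tr in seq_len(d[1])) for (ch in seq_len(d[2]))
      if (!(tr == 1 && ch == 1)) out[tr, ch, ] <- fun(x$data[tr, ch, ])
    rate <- if (is.null(new_rate)) x$rate else new_rate
    return(eeg_epochs(out, rate, x$labels, t_start_ms = x$time_ms[1],
                      subject_id = x$subject_id, group = x$group))
  }
  stop("expected an eeg_recording or eeg_epochs object")
}

# FFT-based resampling of one vector (spectral truncation, anti-aliased by
# construction; equivalent to the classical Fourier-method resampler).
.fft_resample_vec <- function(v, n_out) {
  n <- length(v)
  if (n_out == n) return(v)
  X <- stats::fft(v)
  Y <- complex(n_out)
  half <- floor(min(n, n_out) / 2)
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  }
  if (min(n, n_out) %% 2 == 0) {  # split the shared Nyquist bin
    k <- half + 1
    if (n_out < n) {
      Y[k] <- (X[k] + X[n - half + 1]) / 2
    } else if (n_out > n) {
      Y[k] <- X[k] / 2
      Y[n_out - half + 1] <- X[k] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) * (n_out / n) / n_out
}

#' Resample a recording (downsampling only)
#'
#' Fourier-method resampling: the spectrum is truncated at the new Nyquist
#' frequency, which is inherently anti-aliasing. Duration is preserved
#' within one output sample.
#'
#' @param x an [eeg_recording()] or [eeg_epochs()].
#' @param target_rate new rate in Hz, at most the current rate.
#' @return the resampled object.
#' @export
resample_eeg <- function(x, target_rate) {
  if (target_rate > x$rate)
    stop("upsampling is outside the pipeline's contract (target ",
         target_rate, " > ", x$rate, " Hz)")
  if (target_rate == x$rate) return(x)
  n_in <- if (inherits(x, "eeg_recording")) ncol(x$data) else dim(x$data)[3]
  n_out <- round(n_in * target_rate / x$rate)
  .map_samples(x, function(v) .fft_resample_vec(v, n_out),
               new_rate = target_rate)
}

#' Zero-phase band-limiting
#'
#' 4th-order Butterworth high-pass at `hp_cutoff` and low-pass at
#' `lp_cutoff`, applied as a zero-phase (forward-backward-equivalent)
#' filter: the squared Butterworth magnitude response
#' `|H(f)|^2 = 1/(1 + (hp/f)^(2*order)) * 1/(1 + (f/lp)^(2*order))`
#' is applied in the frequency domain, so the effective attenuation is that
#' of an 8th-order filter and the group delay is exactly zero (no phase
#' distortion of ERD latencies). Channels of a trial are filtered in one
#' batched FFT.
#'
#' @param x an [eeg_recording()] or [eeg_epochs()].
#' @param hp_cutoff,lp_cutoff corner frequencies in Hz.
#' @param order Butterworth order of each pass (default 4).
#' @return the filtered object.
#' @export
bandlimit <- function(x, hp_cutoff = 7, lp_cutoff = 35, order = 4) {
  nyq <- x$rate / 2
  if (hp_cutoff >= nyq || lp_cutoff >= nyq)
    stop("filter cutoffs must lie below the Nyquist frequency (", nyq, " Hz)")
  if (hp_cutoff >= lp_cutoff) stop("hp_cutoff must be below lp_cutoff")
  n <- if (inherits(x, "eeg_recording")) ncol(x$data) else dim(x$data)[3]
  f <- seq(0, n - 1) * x$rate / n
  f <- pmin(f, x$rate - f)
  mag2 <- ifelse(f == 0, 0, 1 / (1 + (hp_cutoff / pmax(f, 1e-12))^(2 * order))) *
    1 / (1 + (f / lp_cutoff)^(2 * order))
  filt_mat <- function(m) {           # samples x channels
    Re(stats::mvfft(stats::mvfft(m) * mag2, inverse = TRUE)) / n
  }
  if (inherits(x, "eeg_recording")) {
    x$data <- t(filt_mat(t(x$data)))
    return(x)
  }
  stopifnot(inherits(x, "eeg_epochs"))
  for (tr in seq_len(dim(x$data)[1]))
    x$data[tr, , ] <- t(filt_mat(t(x$data[tr, , ])))
  x
}

#' Robust channel rejection and spatial interpolation
#'
#' A channel is rejected when its robust amplitude (MAD of its samples,
#' pooled over trials) exceeds `reject_sd` times the median robust amplitude
#' across channels. Rejected channels are rebuilt by inverse-distance-
#' weighted averaging of their `k` nearest neighbours on the 10-20 layout;
#' channel count and order are preserved. This is a deliberately simple
#' stand-in for subspace artifact-reconstruction methods, interface-
#' compatible so one could be substituted.
#'
#' @param x an [eeg_recording()] or [eeg_epochs()].
#' @param reject_sd rejection threshold (default 10).
#' @param k number of neighbours used for interpolation.
#' @return list with `data` (the cleaned object) and `rejected` (labels).
#' @export
reject_and_interpolate <- function(x, reject_sd = 10, k = 4) {
  labels <- x$labels
  if (length(labels) < 4) stop("need at least 4 channels")
  amp <- vapply(seq_along(labels), function(ci) {
    v <- if (inherits(x, "eeg_recording")) x$data[ci, ] else x$data[, ci, ]
    stats::mad(as.numeric(v))
  }, numeric(1))
  ref <- stats::median(amp)
  bad <- which(amp > reject_sd * ref)
  if (length(bad) > 0.25 * length(labels))
    stop("more than 25% of channels rejected (",
         paste(labels[bad], collapse = ", "), "): recording unusable")
  good <- setdiff(seq_along(labels), bad)
  for (ci in bad) {
    nb <- .nearest_neighbours(labels[ci], labels[good], k = k)
    ni <- match(nb$labels, labels)
    if (inherits(x, "eeg_recording")) {
      x$data[ci, ] <- as.numeric(crossprod(nb$weights,
                                           x$data[ni, , drop = FALSE]))
    } else {
      acc <- 0
      for (j in seq_along(ni)) acc <- acc + nb$weights[j] * x$data[, ni[j], ]
      x$data[, ci, ] <- acc
    }
  }
  list(data = x, rejected = labels[bad])
}

#' Cut a continuous recording into epochs around event onsets
#'
#' Epochs span `[span_ms[1], span_ms[2])` (half-open, so every trial has
#' the same sample count). Events whose epoch would cross a recording edge
#' are dropped with a warning.
#'
#' @param recording an [eeg_recording()].
#' @param events data.frame with column `onset_sample` (1-based cue sample).
#' @param span_ms epoch span in ms relative to the cue.
#' @return an [eeg_epochs()]; trials are ordered by event time.
#' @export
epoch_recording <- function(recording, events, span_ms = c(-1000, 5000)) {
  stopifnot(inherits(recording, "eeg_recording"))
  rate <- recording$rate
  pre <- round(-span_ms[1] * rate / 1000)
  post <- round(span_ms[2] * rate / 1000)
  n <- ncol(recording$data)
  onsets <- sort(events$onset_sample)
  keep <- onsets - pre >= 1 & onsets + post - 1 <= n
  if (any(!keep))
    warning(sum(!keep), " event(s) too close to the recording edge dropped")
  onsets <- onsets[keep]
  if (length(onsets) == 0) stop("no event has a full epoch inside the recording")
  nc <- nrow(recording$data)
  len <- pre + post
  dat <- array(0, c(length(onsets), nc, len))
  for (i in seq_along(onsets)) {
    sl <- (onsets[i] - pre):(onsets[i] + post - 1)
    dat[i, , ] <- recording$data[, sl]
  }
  eeg_epochs(dat, rate, recording$labels, t_start_ms = span_ms[1],
             subject_id = recording$subject_id, group = recording$group)
}

#' Common average reference
#'
#' Subtracts, at every time point (and trial), the instantaneous mean across
#' channels; afterwards the channel mean is zero everywhere. Idempotent.
#'
#' @param x an [eeg_epochs()] (or [eeg_recording()]).
#' @return the re-referenced object.
#' @export
common_average_reference <- function(x) {
  if (inherits(x, "eeg_recording")) {
    if (nrow(x$data) < 2) stop("need at least 2 channels")
    x$data <- sweep(x$data, 2, colMeans(x$data))
    return(x)
  }
  stopifnot(inherits(x, "eeg_epochs"))
  if (dim(x$data)[2] < 2) stop("need at least 2 channels")
  for (tr in seq_len(dim(x$data)[1])) {
    m <- x$data[tr, , ]
    x$data[tr, , ] <- sweep(m, 2, colMeans(m))
  }
  x
}

#' Keep only subjects with enough valid trials
#'
#' @param cohort list of [eeg_epochs()] objects.
#' @param min_valid_trials inclusion threshold (inclusive: a subject with
#'   exactly `min_valid_trials` is kept).
#' @return the retained sublist; excluded subjects are reported via message.
#' @export
filter_subjects <- function(cohort, min_valid_trials = 20) {
  nv <- vapply(cohort, function(r) r$n_valid_trials, numeric(1))
  drop <- nv < min_valid_trials
  if (any(drop)) {
    ids <- vapply(cohort[drop], function(r) r$subject_id, character(1))
    message("excluded ", sum(drop), " subject(s) below ", min_valid_trials,
            " valid trials: ", paste(ids, collapse = ", "))
  }
  out <- cohort[!drop]
  if (length(out) == 0) stop("no subject satisfies the inclusion criterion")
  out
}

#' Run the full preprocessing chain on one subject
#'
#' Resample, band-limit, reject/interpolate bad channels, re-reference
#' (common average). Accepts epoched input (synthetic cohorts) or a
#' continuous recording plus events (EDF path), in which case epoching
#' happens after band-limiting.
#'
#' @param x [eeg_epochs()] or [eeg_recording()].
#' @param config a [preprocess_config()].
#' @param events event table, required when `x` is continuous.
#' @return list with `epochs` (clean [eeg_epochs()]) and `rejected`
#'   (channel labels interpolated away).
#' @export
preprocess_subject <- function(x, config = preprocess_config(),
                               events = NULL) {
  orig_rate <- x$rate
  x <- resample_eeg(x, config$target_rate)
  x <- bandlimit(x, config$hp_cutoff, config$lp_cutoff)
  ri <- reject_and_interpolate(x, config$reject_sd)
  x <- ri$data
  if (inherits(x, "eeg_recording")) {
    if (is.null(events)) stop("continuous input requires an event table")
    ev <- events
    ev$onset_sample <- round((ev$onset_sample - 1) *
                               config$target_rate / orig_rate) + 1
    x <- epoch_recording(x, ev)
  }
  x <- common_average_reference(x)
  list(epochs = x, rejected = ri$rejected)
}
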