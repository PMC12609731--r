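# Morlet-wavelet ERSP with two-stage baseline correction:
#  1. per-trial power maps (complex Morlet convolution, unit-energy
#     wavelets, edge cells masked where the wavelet support leaves the
#     epoch),
#  2. per-trial full-epoch baseline division (per frequency),
#  3. trial averaging,
#  4. pre-stimulus baseline division + 10*log10 (dB; negative = ERD).

.cycle_anchors <- list(f = c(7, 30), c = c(3, 20))

#' Cycle count of the Morlet wavelet at a frequency
#'
#' Linear law anchored at 3 cycles at 7 Hz rising to 20 cycles at 30 Hz.
#'
#' @param f frequency (Hz), within `[7, 30]`.
#' @return cycle count.
#' @export
morlet_cycles <- function(f) {
  a <- .cycle_anchors
  if (any(f < a$f[1] - 1e-9 | f > a$f[2] + 1e-9))
    stop("frequency grid outside the analysis range [7, 30] Hz")
  a$c[1] + (a$c[2] - a$c[1]) * (f - a$f[1]) / (a$f[2] - a$f[1])
}

#' Build a wavelet analysis plan
#'
#' @param rate sampling rate of the epochs (Hz); must be at least twice the
#'   top analysis frequency.
#' @param f_min,f_max analysis band edges (default 7 and 30 Hz).
#' @param f_step frequency grid spacing (default 0.5 Hz).
#' @param time_decim output time-grid decimation factor; the default
#'   `round(rate/32)` yields a 32 Hz output grid (187.5 points/6 s epoch at
#'   512 Hz) that contains the cue, 500 ms and 2000 ms exactly.
#' @param support_sd wavelet truncation half-width in temporal SDs.
#' @return list of class `wavelet_plan` with `freqs`, `cycles`, `rate`,
#'   `time_decim`.
#' @export
wavelet_plan <- function(rate, f_min = 7, f_max = 30, f_step = 0.5,
                         time_decim = max(1L, round(rate / 32)),
                         support_sd = 4) {
  if (rate < 2 * f_max)
    stop("sampling rate must be at least twice the top analysis frequency")
  freqs <- seq(f_min, f_max, by = f_step)
  structure(list(freqs = freqs, cycles = morlet_cycles(freqs),
                 rate = rate, time_decim = as.integer(time_decim),
                 support_sd = support_sd),
            class = "wavelet_plan")
}

# wavelet bank for epochs of n samples: padded-FFT matrix (nfft x nf),
# per-frequency half-support h. Memoised: the bank is reused across trials
# and subjects.
.swersp_cache <- new.env(parent = emptyenv())

.wavelet_bank <- function(plan, n) {
  key <- paste(plan$rate, n, plan$time_decim, plan$support_sd,
               length(plan$freqs), plan$freqs[1],
               plan$freqs[length(plan$freqs)], sep = "|")
  hit <- .swersp_cache[[key]]
  if (!is.null(hit)) return(hit)
  rate <- plan$rate
  sig_t <- plan$cycles / (2 * pi * plan$freqs)
  h <- pmax(1L, as.integer(ceiling(plan$support_sd * sig_t * rate)))
  nfft <- 2^ceiling(log2(n + 2 * max(h)))
  bank <- matrix(0 + 0i, nfft, length(plan$freqs))
  for (k in seq_along(plan$freqs)) {
    tt <- seq(-h[k], h[k]) / rate
    psi <- exp(-tt^2 / (2 * sig_t[k]^2)) *
      exp(2i * pi * plan$freqs[k] * tt)
    psi <- psi / sqrt(sum(Mod(psi)^2) / rate)  # unit energy
    bank[seq_along(psi), k] <- psi
  }
  out <- list(W = stats::mvfft(bank), h = h, nfft = nfft)
  .swersp_cache[[key]] <- out
  out
}

#' Per-trial Morlet power map
#'
#' Complex Morlet convolution magnitude squared on the plan's grid. Cells
#' whose wavelet support crosses the epoch boundary are masked (`valid =
#' FALSE`), not zero-filled.
#'
#' @param x sample vector of one epoch for one channel (uV).
#' @param plan a [wavelet_plan()] built for the epoch's sampling rate.
#' @param time_ms time axis of `x` (ms relative to the cue).
#' @param channel channel label stored in the result.
#' @return a [tfr_map()] at stage `raw_power` on the decimated time grid.
#' @export
trial_power <- function(x, plan, time_ms = NULL, channel = "C3") {
  stopifnot(inherits(plan, "wavelet_plan"))
  if (anyNA(x)) stop("input contains NA samples")
  n <- length(x)
  if (is.null(time_ms)) time_ms <- -1000 + (seq_len(n) - 1) * 1000 / plan$rate
  bank <- .wavelet_bank(plan, n)
  X <- stats::fft(c(x, numeric(bank$nfft - n)))
  Z <- stats::mvfft(bank$W * X, inverse = TRUE) / bank$nfft
  idx <- seq(1L, n, by = plan$time_decim)
  nf <- length(plan$freqs)
  vals <- matrix(0, length(idx), nf)
  valid <- matrix(FALSE, length(idx), nf)
  for (k in seq_len(nf)) {
    h <- bank$h[k]
    vals[, k] <- Mod(Z[idx + h, k])^2
    valid[, k] <- idx > h & idx <= n - h
  }
  tfr_map(vals, time_ms[idx], plan$freqs, channel, stage = "raw_power",
          valid = valid, n_trials = 1L)
}

#' Single-trial full-epoch baseline correction
#'
#' Divides each frequency row of a per-trial power map by that row's mean
#' over all valid times, damping trial-level outliers before averaging.
#'
#' @param map a [tfr_map()] at stage `raw_power`.
#' @param center `"mean"` (default) or `"median"`.
#' @return a [tfr_map()] at stage `trial_normalized` (row means 1 when
#'   `center = "mean"`).
#' @export
full_epoch_baseline <- function(map, center = c("mean", "median")) {
  stopifnot(inherits(map, "tfr_map"), map$stage == "raw_power")
  center <- match.arg(center)
  cfun <- if (center == "mean") mean else stats::median
  for (k in seq_along(map$freqs)) {
    v <- map$valid[, k]
    if (!any(v)) stop("frequency row with no valid cells")
    m <- cfun(map$values[v, k])
    map$values[, k] <- map$values[, k] / m
  }
  map$stage <- "trial_normalized"
  map
}

#' Average trial-normalized maps
#'
#' Pointwise mean over trials (masked cells ignored); all maps must share
#' the time/frequency grid and channel.
#'
#' @param maps list of [tfr_map()] at stage `trial_normalized`.
#' @param min_trials minimum number of maps required.
#' @return a [tfr_map()] at stage `averaged` with `n_trials` recorded.
#' @export
average_trials <- function(maps, min_trials = 1) {
  stopifnot(length(maps) >= min_trials, length(maps) >= 1)
  ref <- maps[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  cnt <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (m in maps) {
    stopifnot(inherits(m, "tfr_map"), m$stage == "trial_normalized")
    if (!.same_grid(ref, m) || !identical(ref$channel, m$channel))
      stop("trial maps do not share grid/channel")
    acc <- acc + ifelse(m$valid, m$values, 0)
    cnt <- cnt + m$valid
  }
  vals <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  tfr_map(vals, ref$time_ms, ref$freqs, ref$channel, stage = "averaged",
          valid = cnt > 0, n_trials = length(maps))
}

#' Pre-stimulus dB baseline correction
#'
#' Divides each frequency row of a trial-averaged map by its mean over the
#' pre-stimulus window, then takes `10*log10`. Negative values indicate
#' event-related desynchronization, positive ones synchronization.
#'
#' @param map a [tfr_map()] at stage `averaged`.
#' @param baseline_ms baseline window, default `c(-1000, 0)` ms.
#' @param min_samples minimum valid baseline samples per frequency.
#' @return a [tfr_map()] at stage `db_corrected`.
#' @export
prestimulus_db_correction <- function(map, baseline_ms = c(-1000, 0),
                                      min_samples = 10) {
  stopifnot(inherits(map, "tfr_map"), map$stage == "averaged")
  in_bl <- map$time_ms >= baseline_ms[1] & map$time_ms <= baseline_ms[2]
  for (k in seq_along(map$freqs)) {
    sel <- in_bl & map$valid[, k]
    if (sum(sel) < min_samples)
      stop("fewer than ", min_samples, " valid baseline samples at ",
           map$freqs[k], " Hz")
    mu <- mean(map$values[sel, k])
    if (!is.finite(mu) || mu <= 0)
      stop("nonpositive baseline mean at ", map$freqs[k], " Hz")
    map$values[, k] <- 10 * log10(map$values[, k] / mu)
  }
  map$values[!map$valid] <- NA_real_
  map$stage <- "db_corrected"
  map
}

#' Full ERSP computation for one subject
#'
#' Runs the trial-power / full-epoch-baseline / average / pre-stimulus-dB
#' chain for each requested channel.
#'
#' @param epochs an [eeg_epochs()].
#' @param plan a [wavelet_plan()] matching `epochs$rate`.
#' @param channels channel labels to analyze (default sensorimotor trio).
#' @param baseline_ms pre-stimulus window.
#' @return named list of `db_corrected` [tfr_map()]s.
#' @export
subject_ersp <- function(epochs, plan = wavelet_plan(epochs$rate),
                         channels = c("C3", "Cz", "C4"),
                         baseline_ms = c(-1000, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (abs(plan$rate - epochs$rate) > 1e-9)
    stop("wavelet plan was built for a different sampling rate")
  missing_ch <- setdiff(channels, epochs$labels)
  if (length(missing_ch) > 0)
    stop("channels not present: ", paste(missing_ch, collapse = ", "))
  out <- list()
  for (ch in channels) {
    ci <- match(ch, epochs$labels)
    maps <- lapply(seq_len(dim(epochs$data)[1]), function(tr)
      full_epoch_baseline(
        trial_power(epochs$data[tr, ci, ], plan, epochs$time_ms, ch)))
    avg <- average_trials(maps)
    out[[ch]] <- prestimulus_db_correction(avg, baseline_ms)
  }
  out
}
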