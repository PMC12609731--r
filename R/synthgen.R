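# Synthetic swallowing-EEG generator.
#
# Signal model per trial and channel:
#   x(t) = b(t) + g_a(t) * a(t) + g_b(t) * m(t)
# where b is 1/f background noise, a and m are narrowband Gaussian
# oscillators (band-passed white noise) occupying the alpha and beta
# analysis bands, and g(t) = 1 - depth * w(t) with w a raised-cosine
# suppression window. Amplitude-modulated narrowband noise (not sinusoids)
# keeps the spectral width realistic so ERSP estimates are not trivially
# sharp.

# The alpha-range oscillator deliberately overfills the 7-13 Hz analysis
# band (mu-rhythm-like, centered ~10 Hz): wavelet bandwidths at 3-8 cycles
# are 1.5-2.5 Hz, so analysis bins at the band edges mostly see oscillator
# rather than out-of-band background, keeping the band-average suppression
# close to its aggregate analytic value.
.alpha_osc_band <- c(6, 14)
.beta_osc_band <- c(13, 30)
.bg_band_lo <- 1
.bg_band_hi <- 100
.depth_cap <- 0.95

#' Group generative profile
#'
#' Describes one cohort group: per-channel fractional amplitude suppression
#' (ERD depth) in the alpha and beta bands, the timing of the suppression
#' window, oscillator and background amplitudes, and the between-subject /
#' between-channel variability of the depths.
#'
#' @param name group label, e.g. "healthy", "control", "dysphagic".
#' @param alpha_depth,beta_depth named numeric vectors of fractional
#'   amplitude suppression in `[0, 1)`, names are channel labels (typically
#'   C3, Cz, C4). Channels not named get depth 0.
#' @param erd_onset_ms,erd_offset_ms start/end of the suppression window,
#'   ms relative to the cue; must lie inside the epoch and satisfy
#'   onset < offset.
#' @param ramp_ms raised-cosine transition duration at each end (ms).
#' @param alpha_amp,beta_amp oscillator RMS amplitude in microvolts.
#' @param background_scale RMS of the 1/f background in microvolts.
#' @param trial_jitter_ms per-trial uniform jitter of the suppression window.
#' @param subject_sd named vector `c(alpha=, beta=)`: between-subject SD of
#'   the depths (shared across channels within a subject and band, emulating
#'   a subject-level band reactivity trait).
#' @param channel_jitter_sd SD of the small independent per-channel depth
#'   perturbation on top of the subject effect.
#' @return object of class `group_profile`.
#' @export
group_profile <- function(name,
                          alpha_depth = c(C3 = 0, Cz = 0, C4 = 0),
                          beta_depth = c(C3 = 0, Cz = 0, C4 = 0),
                          erd_onset_ms = 250, erd_offset_ms = 4000,
                          ramp_ms = 400,
                          alpha_amp = 5, beta_amp = 5,
                          background_scale = 10,
                          trial_jitter_ms = 100,
                          subject_sd = c(alpha = 0, beta = 0),
                          channel_jitter_sd = 0) {
  stopifnot(length(name) == 1, is.numeric(alpha_depth), is.numeric(beta_depth))
  if (is.null(names(alpha_depth)) || is.null(names(beta_depth)))
    stop("depth vectors must be named by channel label")
  if (any(alpha_depth < 0 | alpha_depth >= 1) ||
      any(beta_depth < 0 | beta_depth >= 1))
    stop("depths must lie in [0, 1)")
  if (!(erd_onset_ms < erd_offset_ms))
    stop("erd_onset_ms must be smaller than erd_offset_ms")
  if (erd_onset_ms < -1000 || erd_offset_ms > 5000)
    stop("suppression window must lie inside the epoch [-1000, 5000] ms")
  stopifnot(ramp_ms >= 0, alpha_amp >= 0, beta_amp >= 0,
            background_scale > 0, trial_jitter_ms >= 0,
            all(subject_sd >= 0), channel_jitter_sd >= 0)
  structure(list(name = name,
                 alpha_depth = alpha_depth, beta_depth = beta_depth,
                 erd_onset_ms = erd_onset_ms, erd_offset_ms = erd_offset_ms,
                 ramp_ms = ramp_ms,
                 alpha_amp = alpha_amp, beta_amp = beta_amp,
                 background_scale = background_scale,
                 trial_jitter_ms = trial_jitter_ms,
                 subject_sd = c(alpha = unname(subject_sd["alpha"]),
                                beta = unname(subject_sd["beta"])),
                 channel_jitter_sd = channel_jitter_sd),
            class = "group_profile")
}

#' Built-in group presets
#'
#' Default generative profiles for the three study groups. Depths are chosen
#' so that, through the full pipeline, median ERIs reproduce the expected
#' ordering (healthy strongest ERD, dysphagic weakest), the dysphagic group
#' is laterally asymmetric (C3 shallower than C4), the healthy-vs-control
#' contrast separates in the beta band but not in the alpha band (alpha
#' depths are close and between-subject alpha variability is large), and
#' scalar ERIs land on a dB scale of a few dB.
#'
#' @param name one of "healthy", "control", "dysphagic".
#' @param ... overrides passed on to [group_profile()].
#' @return a `group_profile`.
#' @export
group_preset <- function(name = c("healthy", "control", "dysphagic"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    healthy = list(
      alpha_depth = c(C3 = 0.30, Cz = 0.30, C4 = 0.30),
      beta_depth = c(C3 = 0.42, Cz = 0.42, C4 = 0.42)),
    control = list(
      alpha_depth = c(C3 = 0.18, Cz = 0.18, C4 = 0.18),
      beta_depth = c(C3 = 0.22, Cz = 0.22, C4 = 0.22)),
    dysphagic = list(
      alpha_depth = c(C3 = 0.06, Cz = 0.05, C4 = 0.18),
      beta_depth = c(C3 = 0.06, Cz = 0.05, C4 = 0.18)))
  args <- utils::modifyList(
    c(list(name = name), base,
      list(subject_sd = c(alpha = 0.30, beta = 0.07),
           channel_jitter_sd = 0.02)),
    list(...))
  do.call(group_profile, args)
}

#' Cohort specification
#'
#' @param groups list of `list(profile = <group_profile>, n_subjects = <int>)`.
#' @param n_trials_per_subject trials (cued swallows) per subject.
#' @param n_trials_sd if > 0, per-subject trial counts are drawn from a
#'   normal with this SD, rounded and truncated to `n_trials_range`
#'   (off by default).
#' @param n_trials_range allowed range for heterogeneous trial counts.
#' @param sampling_rate Hz; must exceed 70 Hz (twice the 35 Hz analysis
#'   ceiling).
#' @param n_channels montage size (3 to 32); C3, Cz, C4 always included.
#' @param seed RNG seed for the whole cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, n_trials_per_subject = 40,
                        n_trials_sd = 0, n_trials_range = c(20, 40),
                        sampling_rate = 2000, n_channels = 32, seed = 1) {
  stopifnot(is.list(groups), length(groups) >= 1)
  for (g in groups) {
    if (!inherits(g$profile, "group_profile"))
      stop("each group needs a `profile` of class group_profile")
    if (is.null(g$n_subjects) || g$n_subjects <= 0)
      stop("each group needs n_subjects > 0")
  }
  if (n_trials_per_subject < 1) stop("n_trials_per_subject must be >= 1")
  if (sampling_rate <= 2 * 35) stop("sampling_rate must exceed 70 Hz")
  structure(list(groups = groups,
                 n_trials_per_subject = n_trials_per_subject,
                 n_trials_sd = n_trials_sd, n_trials_range = n_trials_range,
                 sampling_rate = sampling_rate,
                 n_channels = n_channels,
                 epoch_span_ms = c(-1000, 5000),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Stationary Gaussian noise synthesized in the frequency domain: each FFT
# bin gets an independent complex-normal coefficient weighted by the target
# amplitude spectrum, and the real part of the inverse transform is a
# Gaussian process with PSD proportional to h^2. The shape matrix (three
# components: 1/f background, alpha and beta band noise) is cached per
# (n, rate); columns are scaled so each component's variance is exactly 1
# before multiplication by the requested RMS.

.noise_shapes <- new.env(parent = emptyenv())

# per (n, rate): for each component (1/f background, alpha osc, beta osc),
# the indices of FFT bins inside the component's band and the amplitude
# weights there, scaled so the synthesized process has unit variance.
.noise_shape <- function(n, rate) {
  key <- paste(n, rate, sep = "|")
  hit <- .noise_shapes[[key]]
  if (!is.null(hit)) return(hit)
  f <- seq(0, n - 1) * rate / n
  f <- pmin(f, rate - f)
  hi <- min(.bg_band_hi, 0.95 * rate / 2)
  mk <- function(amp) {
    idx <- which(amp > 0)
    w <- amp[idx] * n / sqrt(sum(amp[idx]^2))
    list(idx = idx, w = w)
  }
  out <- list(
    bg = mk(ifelse(f >= .bg_band_lo & f <= hi,
                   1 / sqrt(pmax(f, .bg_band_lo)), 0)),
    alpha = mk(as.numeric(f >= .alpha_osc_band[1] & f <= .alpha_osc_band[2])),
    beta = mk(as.numeric(f >= .beta_osc_band[1] & f <= .beta_osc_band[2])))
  .noise_shapes[[key]] <- out
  out
}

# draws the three noise components for `nch` channels of one trial:
# independent complex-normal coefficients on the in-band FFT bins, one
# batched inverse FFT. Returns an n x (3*nch) real matrix with unit-RMS
# columns ordered (bg, alpha, beta) per channel.
.noise_components <- function(n, rate, nch = 1L) {
  sh <- .noise_shape(n, rate)
  z <- matrix(0i, n, 3L * nch)
  for (ci in seq_len(nch)) {
    for (k in 1:3) {
      s <- sh[[k]]
      m <- length(s$idx)
      z[s$idx, 3L * (ci - 1L) + k] <-
        s$w * complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    }
  }
  Re(stats::mvfft(z, inverse = TRUE)) / n
}

# raised-cosine suppression window on a ms time axis
.erd_window <- function(t_ms, onset, offset, ramp) {
  w <- numeric(length(t_ms))
  ramp <- min(ramp, (offset - onset) / 2)
  up <- t_ms >= onset & t_ms < onset + ramp
  flat <- t_ms >= onset + ramp & t_ms <= offset - ramp
  down <- t_ms > offset - ramp & t_ms <= offset
  if (ramp > 0) {
    w[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - onset) / ramp))
    w[down] <- 0.5 * (1 - cos(pi * (offset - t_ms[down]) / ramp))
  }
  w[flat] <- 1
  w
}

#' Generate one synthetic trial for one channel
#'
#' Returns the sample vector of a single epoch (cue at t = 0; the epoch
#' starts 1000 ms before the cue): 1/f background plus alpha and beta
#' narrowband oscillators whose amplitude is multiplied by
#' `1 - depth * w(t)`, `w` a raised-cosine window. Channels without a
#' specified depth get depth 0.
#'
#' @param profile a [group_profile()].
#' @param channel channel label (must belong to the 10-20 montage).
#' @param duration_ms epoch duration in ms (default 6000, spanning
#'   -1000..5000 ms around the cue).
#' @param rate_hz sampling rate in Hz.
#' @param seed optional integer; when given, the trial is a pure function of
#'   `(profile, channel, seed)`.
#' @return numeric vector of `duration_ms * rate_hz / 1000` samples (uV).
#' @export
generate_trial <- function(profile, channel, duration_ms = 6000,
                           rate_hz = 2000, seed = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  if (!channel %in% .montage32$label)
    stop("unknown channel label: ", channel)
  gen <- function() .generate_trial_impl(profile, channel, duration_ms, rate_hz)
  if (!is.null(seed)) withr::with_seed(as.integer(seed), gen()) else gen()
}

.generate_trial_impl <- function(profile, channel, duration_ms, rate_hz) {
  n <- round(duration_ms * rate_hz / 1000)
  t_ms <- -1000 + (seq_len(n) - 1) * 1000 / rate_hz
  jit <- if (profile$trial_jitter_ms > 0)
    stats::runif(1, -profile$trial_jitter_ms, profile$trial_jitter_ms) else 0
  w <- .erd_window(t_ms, profile$erd_onset_ms + jit,
                   profile$erd_offset_ms + jit, profile$ramp_ms)
  da <- if (channel %in% names(profile$alpha_depth))
    unname(profile$alpha_depth[channel]) else 0
  db <- if (channel %in% names(profile$beta_depth))
    unname(profile$beta_depth[channel]) else 0
  nc <- .noise_components(n, rate_hz, 1L)
  profile$background_scale * nc[, 1] +
    profile$alpha_amp * (1 - da * w) * nc[, 2] +
    profile$beta_amp * (1 - db * w) * nc[, 3]
}

#' Generate an epoched recording for one subject
#'
#' @param profile a [group_profile()] (already subject-adjusted if desired).
#' @param n_trials number of trials.
#' @param rate_hz sampling rate.
#' @param channel_labels montage labels.
#' @param seed integer seed; the subject is fully reproducible from it.
#' @param subject_id,group identifiers stored in the result.
#' @return an [eeg_epochs()] object.
#' @export
generate_subject <- function(profile, n_trials = 40, rate_hz = 2000,
                             channel_labels = default_channel_labels(32),
                             seed = 1, subject_id = "S01",
                             group = profile$name) {
  bad <- setdiff(channel_labels, .montage32$label)
  if (length(bad) > 0)
    stop("unknown channel label: ", paste(bad, collapse = ", "))
  n <- round(6000 * rate_hz / 1000)
  nch <- length(channel_labels)
  t_ms <- -1000 + (seq_len(n) - 1) * 1000 / rate_hz
  dep <- function(depths, ch)
    if (ch %in% names(depths)) unname(depths[ch]) else 0
  da <- vapply(channel_labels, dep, numeric(1), depths = profile$alpha_depth)
  db <- vapply(channel_labels, dep, numeric(1), depths = profile$beta_depth)
  dat <- array(0, dim = c(n_trials, nch, n))
  withr::with_seed(as.integer(seed), {
    for (tr in seq_len(n_trials)) {
      # the suppression-window jitter models swallow-timing variability,
      # so it is drawn per trial and shared by all channels
      jit <- if (profile$trial_jitter_ms > 0)
        stats::runif(1, -profile$trial_jitter_ms, profile$trial_jitter_ms)
      else 0
      w <- .erd_window(t_ms, profile$erd_onset_ms + jit,
                       profile$erd_offset_ms + jit, profile$ramp_ms)
      comps <- .noise_components(n, rate_hz, nch)
      for (ci in seq_len(nch)) {
        j <- 3L * (ci - 1L)
        dat[tr, ci, ] <- profile$background_scale * comps[, j + 1L] +
          profile$alpha_amp * (1 - da[ci] * w) * comps[, j + 2L] +
          profile$beta_amp * (1 - db[ci] * w) * comps[, j + 3L]
      }
    }
  })
  eeg_epochs(dat, rate_hz, channel_labels, t_start_ms = -1000,
             subject_id = subject_id, group = group)
}

# subject-level depth adjustment: shared band factor z (quantile-stratified
# across the group) plus small independent per-channel jitter.
.adjust_profile <- function(profile, z, chan_jitter) {
  adj <- function(depths, sd_band) {
    if (sd_band == 0 && profile$channel_jitter_sd == 0) return(depths)
    out <- depths
    for (ch in names(depths)) {
      if (depths[ch] > 0 || sd_band > 0) {
        j <- if (profile$channel_jitter_sd > 0) chan_jitter[ch] else 0
        out[ch] <- min(max(depths[ch] + sd_band * z + j, 0), .depth_cap)
      }
    }
    out
  }
  profile$alpha_depth <- adj(profile$alpha_depth, profile$subject_sd["alpha"])
  profile$beta_depth <- adj(profile$beta_depth, profile$subject_sd["beta"])
  profile$subject_sd <- c(alpha = 0, beta = 0)
  profile$channel_jitter_sd <- 0
  profile
}

# deterministic per-subject seed, below 2^31
.subject_seed <- function(base_seed, index) {
  (as.integer(base_seed) + 7919L * as.integer(index)) %% 2000000011L
}

#' Generate a full synthetic cohort
#'
#' One epoched recording per subject. Between-subject heterogeneity of the
#' suppression depths uses quantile-stratified normal draws per group (the
#' group's subject effects sit on permuted normal quantiles), so finite
#' cohorts represent the target depth distribution without Monte-Carlo
#' drift. Per-subject signal streams are seeded independently from the
#' cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @param callback optional `function(recording, meta_row)` called per
#'   subject; when supplied, recordings are not accumulated (constant-memory
#'   streaming for large cohorts) and only metadata is returned.
#' @return list with `recordings` (list of [eeg_epochs()], empty in
#'   streaming mode) and `metadata` (data.frame: subject_id, group,
#'   n_trials, subject_seed).
#' @export
generate_cohort <- function(spec, callback = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- default_channel_labels(spec$n_channels)
  recs <- list()
  meta <- list()
  idx <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    n <- g$n_subjects
    # group-level draws: permutation of stratified quantiles, trial counts
    grp <- withr::with_seed(.subject_seed(spec$seed, 100000L + gi), {
      z <- stats::qnorm((seq_len(n) - 0.5) / n)[sample.int(n)]
      nt <- rep(spec$n_trials_per_subject, n)
      if (spec$n_trials_sd > 0) {
        nt <- round(stats::rnorm(n, spec$n_trials_per_subject,
                                 spec$n_trials_sd))
        nt <- pmin(pmax(nt, spec$n_trials_range[1]), spec$n_trials_range[2])
      }
      list(z = z, nt = nt)
    })
    for (si in seq_len(n)) {
      idx <- idx + 1L
      sseed <- .subject_seed(spec$seed, idx)
      chj <- withr::with_seed(sseed + 1L, {
        j <- stats::rnorm(length(labels), 0, g$profile$channel_jitter_sd)
        names(j) <- labels
        j
      })
      prof_i <- .adjust_profile(g$profile, grp$z[si], chj)
      sid <- sprintf("%s_%02d", g$profile$name, si)
      rec <- generate_subject(prof_i, grp$nt[si], spec$sampling_rate,
                              labels, seed = sseed, subject_id = sid,
                              group = g$profile$name)
      row <- data.frame(subject_id = sid, group = g$profile$name,
                        n_trials = grp$nt[si], subject_seed = sseed,
                        stringsAsFactors = FALSE)
      meta[[idx]] <- row
      if (is.null(callback)) recs[[idx]] <- rec else callback(rec, row)
    }
  }
  list(recordings = recs, metadata = do.call(rbind, meta))
}

#' Analytic plateau ERSP expectation for a synthetic profile
#'
#' Expected dB value of the band-averaged, baseline-corrected ERSP inside
#' the suppression plateau:
#' `10*log10((P_bg + (1-d)^2 * P_osc) / (P_bg + P_osc))`, with `P_osc` the
#' oscillator power (RMS^2) and `P_bg` the 1/f background power falling in
#' the band.
#'
#' Both `P_osc` and `P_bg` are the shares falling inside the analysis band
#' (7-13 / 13-30 Hz); the oscillators have flat in-band spectra, so the
#' oscillator share is the band-overlap fraction of `amp^2`.
#'
#' @param profile a [group_profile()].
#' @param band "alpha" or "beta".
#' @param channel channel label.
#' @param rate_hz sampling rate (sets the upper background band edge).
#' @return expected plateau value in dB (negative = desynchronization).
#' @export
expected_plateau_db <- function(profile, band = c("alpha", "beta"),
                                channel = "C3", rate_hz = 512) {
  band <- match.arg(band)
  osc_band <- if (band == "alpha") .alpha_osc_band else .beta_osc_band
  ana_band <- if (band == "alpha") c(7, 13) else c(13, 30)
  amp <- if (band == "alpha") profile$alpha_amp else profile$beta_amp
  depths <- if (band == "alpha") profile$alpha_depth else profile$beta_depth
  d <- if (channel %in% names(depths)) unname(depths[channel]) else 0
  hi <- min(.bg_band_hi, 0.95 * rate_hz / 2)
  p_bg <- profile$background_scale^2 *
    log(ana_band[2] / ana_band[1]) / log(hi / .bg_band_lo)
  overlap <- max(0, min(osc_band[2], ana_band[2]) -
                   max(osc_band[1], ana_band[1]))
  p_osc <- amp^2 * overlap / (osc_band[2] - osc_band[1])
  10 * log10((p_bg + (1 - d)^2 * p_osc) / (p_bg + p_osc))
}
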