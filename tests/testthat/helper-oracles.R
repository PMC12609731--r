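# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (direct convolution instead of FFT,
# Hilbert envelopes instead of wavelets, exhaustive enumeration instead of
# closed-form distributions).

# analytic signal via the standard frequency-domain Hilbert construction
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# mean band power of x inside a frequency band, via Hilbert envelope of the
# hard band-passed signal, restricted to a sample index window
hilbert_band_power <- function(x, rate, band, idx = seq_along(x)) {
  n <- length(x)
  f <- seq(0, n - 1) * rate / n
  f <- pmin(f, rate - f)
  X <- stats::fft(x)
  X[!(f >= band[1] & f <= band[2])] <- 0
  xb <- Re(stats::fft(X, inverse = TRUE)) / n
  env2 <- Mod(hilbert_analytic(xb))^2
  mean(env2[idx]) / 2  # envelope^2 / 2 = instantaneous power of the band signal
}

# direct (time-domain) complex Morlet convolution power at given sample
# indices, mirroring the package's wavelet definition independently
direct_morlet_power <- function(x, f, cycles, rate, idx, support_sd = 4) {
  sig_t <- cycles / (2 * pi * f)
  h <- max(1L, as.integer(ceiling(support_sd * sig_t * rate)))
  tt <- seq(-h, h) / rate
  psi <- exp(-tt^2 / (2 * sig_t^2)) * exp(2i * pi * f * tt)
  psi <- psi / sqrt(sum(Mod(psi)^2) / rate)
  vapply(idx, function(i) {
    js <- (i - h):(i + h)
    if (js[1] < 1 || js[length(js)] > length(x)) return(NA_real_)
    # convolution: sum_j x[j] * psi[i - j]
    Mod(sum(x[js] * psi[(i - js) + h + 1]))^2
  }, numeric(1))
}

# exhaustive-enumeration two-sided Mann-Whitney p-value (no ties)
enum_mann_whitney_p <- function(x, y) {
  n_x <- length(x); n_y <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  all_u <- apply(utils::combn(n_x + n_y, n_x), 2, function(ix)
    sum(seq_len(n_x + n_y)[ix]) - n_x * (n_x + 1) / 2)
  p <- min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
  p
}

# exhaustive-enumeration two-sided Wilcoxon signed-rank p-value
# (no zero differences, no tied |d|)
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  all_v <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(all_v <= v_obs), mean(all_v >= v_obs)))
}

# fine-grid Riemann integration oracle for band/window averages of a map
riemann_band_mean <- function(freqs, vals, f1, f2, n_dense = 20000) {
  fd <- seq(f1, f2, length.out = n_dense)
  vd <- stats::approx(freqs, vals, xout = fd)$y
  mean(vd)
}

# small helper: quiet profile without ERD for null-structure tests
flat_profile <- function(...) {
  group_profile("flat", alpha_depth = c(C3 = 0, Cz = 0, C4 = 0),
                beta_depth = c(C3 = 0, Cz = 0, C4 = 0),
                trial_jitter_ms = 0, ...)
}
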