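test_that("trial generation is deterministic and validates channels", {
  p <- group_preset("healthy")
  a <- generate_trial(p, "C3", 6000, 512, seed = 11)
  b <- generate_trial(p, "C3", 6000, 512, seed = 11)
  expect_identical(a, b)
  expect_length(a, 3072)
  expect_error(generate_trial(p, "XX9", 6000, 512, seed = 1), "XX9")

  ep1 <- generate_subject(p, 3, 512, seed = 4, subject_id = "s")
  ep2 <- generate_subject(p, 3, 512, seed = 4, subject_id = "s")
  expect_identical(ep1$data, ep2$data)
})

test_that("without suppression the band envelope is stationary across the epoch", {
  p <- flat_profile()
  rate <- 512
  n_trials <- 40
  pre <- integer(0); post <- integer(0)
  t_ms <- -1000 + (0:3071) * 1000 / rate
  pre_idx <- which(t_ms >= -900 & t_ms <= -100)
  post_idx <- which(t_ms >= 1000 & t_ms <= 3500)
  ratios <- vapply(seq_len(n_trials), function(i) {
    x <- generate_trial(p, "C3", 6000, rate, seed = 1000 + i)
    hilbert_band_power(x, rate, c(7, 13), post_idx) /
      hilbert_band_power(x, rate, c(7, 13), pre_idx)
  }, numeric(1))
  # mean ratio ~ 1 within 3 SE
  se <- stats::sd(ratios) / sqrt(n_trials)
  expect_lt(abs(mean(ratios) - 1), 3 * se + 0.02)
})

test_that("a 3 dB amplitude suppression yields ~3 dB alpha power drop (Hilbert oracle)", {
  d <- 1 - 10^(-3 / 20)  # ~0.2929 amplitude suppression
  p <- group_profile("t", alpha_depth = c(C3 = d), beta_depth = c(C3 = 0),
                     erd_onset_ms = 0, erd_offset_ms = 4500, ramp_ms = 200,
                     trial_jitter_ms = 0, alpha_amp = 8, background_scale = 3)
  rate <- 512
  t_ms <- -1000 + (0:3071) * 1000 / rate
  pre_idx <- which(t_ms >= -900 & t_ms <= -100)
  plat_idx <- which(t_ms >= 500 & t_ms <= 4000)
  n_trials <- 200
  rrs <- vapply(seq_len(n_trials), function(i) {
    x <- generate_trial(p, "C3", 6000, rate, seed = 5000 + i)
    c(hilbert_band_power(x, rate, c(7, 13), plat_idx),
      hilbert_band_power(x, rate, c(7, 13), pre_idx))
  }, numeric(2))
  num <- rrs[1, ]; den <- rrs[2, ]
  meas_db <- 10 * log10(mean(num) / mean(den))
  exp_db <- expected_plateau_db(p, "alpha", "C3", rate)
  # within sampling error of the ensemble (delta-method SE of the dB ratio)
  se_db <- (10 / log(10)) *
    sqrt(stats::var(num) / (n_trials * mean(num)^2) +
           stats::var(den) / (n_trials * mean(den)^2))
  expect_lt(abs(meas_db - exp_db), 3 * se_db)
  # oscillator dominates background here, so expectation is close to -3 dB
  expect_lt(abs(exp_db - (-3)), 0.6)
})

test_that("ensemble plateau/baseline power ratio matches the analytic value within 3 SE", {
  d <- 0.5
  p <- group_profile("t", alpha_depth = c(C3 = d), beta_depth = c(C3 = 0),
                     erd_onset_ms = 0, erd_offset_ms = 4500, ramp_ms = 200,
                     trial_jitter_ms = 0)
  rate <- 512
  t_ms <- -1000 + (0:3071) * 1000 / rate
  pre_idx <- which(t_ms >= -900 & t_ms <= -100)
  plat_idx <- which(t_ms >= 500 & t_ms <= 4000)
  n_trials <- 200
  pw <- vapply(seq_len(n_trials), function(i) {
    x <- generate_trial(p, "C3", 6000, rate, seed = 300 + i)
    c(hilbert_band_power(x, rate, c(7, 13), plat_idx),
      hilbert_band_power(x, rate, c(7, 13), pre_idx))
  }, numeric(2))
  num <- pw[1, ]; den <- pw[2, ]
  r_hat <- mean(num) / mean(den)       # ratio of ensemble means
  expected <- 10^(expected_plateau_db(p, "alpha", "C3", rate) / 10)
  # delta-method standard error of the ratio of means
  se <- r_hat * sqrt(stats::var(num) / (n_trials * mean(num)^2) +
                       stats::var(den) / (n_trials * mean(den)^2) -
                       2 * stats::cov(num, den) /
                         (n_trials * mean(num) * mean(den)))
  expect_lt(abs(r_hat - expected), 3 * se)
})

test_that("plateau band power is non-increasing in suppression depth", {
  rate <- 512
  t_ms <- -1000 + (0:3071) * 1000 / rate
  plat_idx <- which(t_ms >= 500 & t_ms <= 4000)
  powers <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(d) {
    p <- group_profile("t", alpha_depth = c(C3 = d), beta_depth = c(C3 = 0),
                       erd_onset_ms = 0, erd_offset_ms = 4500, ramp_ms = 200,
                       trial_jitter_ms = 0)
    mean(vapply(seq_len(100), function(i) {
      x <- generate_trial(p, "C3", 6000, rate, seed = 40 + i)  # common seeds
      hilbert_band_power(x, rate, c(7, 13), plat_idx)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(powers) < 0))
})

test_that("cohort generation gives the right sizes and is reproducible", {
  groups <- list(
    list(profile = group_preset("healthy"), n_subjects = 2),
    list(profile = group_preset("control"), n_subjects = 3),
    list(profile = group_preset("dysphagic"), n_subjects = 4))
  spec <- cohort_spec(groups, n_trials_per_subject = 2, sampling_rate = 256,
                      n_channels = 4, seed = 9)
  a <- generate_cohort(spec)
  expect_length(a$recordings, 9)
  expect_equal(nrow(a$metadata), 9)
  expect_equal(dim(a$recordings[[1]]$data)[1], 2)
  expect_setequal(unique(a$metadata$group), c("healthy", "control", "dysphagic"))
  b <- generate_cohort(spec)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$recordings[[5]]$data, b$recordings[[5]]$data)
  # streaming callback sees the same subjects
  seen <- character(0)
  generate_cohort(spec, callback = function(rec, row)
    seen <<- c(seen, rec$subject_id))
  expect_identical(seen, a$metadata$subject_id)

  expect_error(cohort_spec(list(list(profile = group_preset("healthy"),
                                     n_subjects = 0)), seed = 1),
               "n_subjects")
  expect_error(cohort_spec(groups, sampling_rate = 60), "70 Hz")
})

test_that("profile invariants are enforced", {
  expect_error(group_profile("x", alpha_depth = c(C3 = 1.0),
                             beta_depth = c(C3 = 0)), "0, 1")
  expect_error(group_profile("x", alpha_depth = c(C3 = 0.1),
                             beta_depth = c(C3 = 0.1),
                             erd_onset_ms = 3000, erd_offset_ms = 2000),
               "onset")
  expect_error(group_profile("x", alpha_depth = c(C3 = 0.1),
                             beta_depth = c(C3 = 0.1),
                             erd_offset_ms = 6000), "epoch")
})
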