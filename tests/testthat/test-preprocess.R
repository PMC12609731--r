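make_rec <- function(x, rate = 2000, labels = NULL) {
  if (is.vector(x)) x <- matrix(x, 1)
  if (is.null(labels)) labels <- default_channel_labels(nrow(x) + 2)[seq_len(nrow(x))]
  eeg_recording(x, rate, labels)
}

test_that("resampling preserves rate arithmetic, DC and sine amplitude", {
  # 2000 Hz, 6 s -> 512 Hz: 3072 samples
  rec <- make_rec(matrix(rnorm(12000), 1), 2000)
  out <- resample_eeg(rec, 512)
  expect_equal(ncol(out$data), 3072)
  expect_equal(out$rate, 512)

  dc <- make_rec(matrix(5, 1, 12000), 2000)
  outdc <- resample_eeg(dc, 512)
  expect_lt(max(abs(outdc$data[1, 100:2900] - 5)) / 5, 1e-6)

  t <- (0:11999) / 2000
  sine <- make_rec(sin(2 * pi * 10 * t), 2000)
  outs <- resample_eeg(sine, 512)
  ref <- sin(2 * pi * 10 * (0:3071) / 512)  # analytically sampled
  interior <- 150:2900
  expect_lt(max(abs(outs$data[1, interior] - ref[interior])), 0.01)

  expect_error(resample_eeg(rec, 4000), "upsampling")
})

test_that("band-limiting matches its zero-phase Butterworth response", {
  rate <- 512
  t <- (0:(6 * rate - 1)) / rate
  mag2 <- function(f, hp = 7, lp = 35, o = 4)
    1 / (1 + (hp / f)^(2 * o)) / (1 + (f / lp)^(2 * o))
  interior <- 500:2500
  for (f0 in c(1, 20, 50)) {
    rec <- make_rec(sin(2 * pi * f0 * t), rate)
    out <- bandlimit(rec)
    ratio <- stats::sd(out$data[1, interior]) / stats::sd(rec$data[1, interior])
    expect_lt(abs(ratio - mag2(f0)), 0.02)
  }
  # the stopband examples: strong attenuation at 1 Hz and 50 Hz
  for (f0 in c(1, 50)) {
    rec <- make_rec(sin(2 * pi * f0 * t), rate)
    out <- bandlimit(rec)
    expect_lt(stats::sd(out$data[1, interior]) / stats::sd(rec$data[1, interior]),
              0.06)
  }
  # no group delay: passband sine keeps its phase (peak correlation at lag 0)
  rec <- make_rec(sin(2 * pi * 20 * t), rate)
  out <- bandlimit(rec)
  cc <- stats::ccf(out$data[1, interior], rec$data[1, interior],
                   lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandlimit(make_rec(rnorm(100), 60)), "Nyquist")
})

test_that("channel rejection flags constructed outliers and interpolates", {
  set.seed(42)
  rate <- 256
  labs <- default_channel_labels(8)
  x <- matrix(rnorm(8 * rate * 2), 8)
  rec <- eeg_recording(x, rate, labs)
  clean <- reject_and_interpolate(rec, reject_sd = 10)
  expect_length(clean$rejected, 0)
  expect_identical(clean$data$data, x)

  bad <- rec
  ci <- match("C3", labs)
  bad$data[ci, ] <- bad$data[ci, ] * 1000
  fixed <- reject_and_interpolate(bad, reject_sd = 10)
  expect_identical(fixed$rejected, "C3")
  expect_identical(fixed$data$labels, labs)      # order preserved
  expect_lt(max(abs(fixed$data$data[ci, ])), 50) # rebuilt at sane scale

  # neighbours carrying an identical signal reproduce it exactly
  s <- sin(2 * pi * 5 * (0:(rate * 2 - 1)) / rate)
  same <- rec
  for (i in seq_len(8)) same$data[i, ] <- s
  same$data[ci, ] <- s * 1000
  out <- reject_and_interpolate(same, reject_sd = 10)
  expect_identical(out$rejected, "C3")
  expect_equal(out$data$data[ci, ], s, tolerance = 1e-12)

  worse <- rec
  worse$data[1:3, ] <- worse$data[1:3, ] * 1000
  expect_error(reject_and_interpolate(worse, reject_sd = 10), "25%")
})

test_that("epoching aligns trials on events and drops edge events", {
  rate <- 500
  n <- rate * 30
  labs <- default_channel_labels(3)
  x <- matrix(rnorm(3 * n), 3)
  rec <- eeg_recording(x, rate, labs)
  onsets <- as.integer(seq(2 * rate, 25 * rate, by = 2 * rate))  # interior
  ev <- data.frame(onset_sample = onsets, label = "cue")
  ep <- epoch_recording(rec, ev)
  expect_equal(dim(ep$data)[1], length(onsets))
  expect_equal(ep$time_ms[1], -1000)
  expect_equal(dim(ep$data)[3], 6 * rate)
  # sample at t = 0 equals the recording sample at the event onset
  i0 <- which(ep$time_ms == 0)
  expect_equal(ep$data[1, 2, i0], x[2, onsets[1]])

  # event 200 ms after start lacks its 1000 ms pre-cue span
  ev2 <- rbind(data.frame(onset_sample = as.integer(0.2 * rate), label = "cue"), ev)
  expect_warning(ep2 <- epoch_recording(rec, ev2), "dropped")
  expect_equal(dim(ep2$data)[1], length(onsets))
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  ep <- generate_subject(flat_profile(), 2, 256, default_channel_labels(4),
                         seed = 8)
  car1 <- common_average_reference(ep)
  mx <- apply(car1$data, c(1, 3), mean)
  expect_lt(max(abs(mx)), 1e-9 * stats::sd(car1$data))
  car2 <- common_average_reference(car1)
  expect_equal(car2$data, car1$data, tolerance = 1e-12)

  # {+1, -1} constant channels unchanged; {2,2,2} -> all zeros
  r <- eeg_recording(rbind(rep(1, 10), rep(-1, 10)), 100, c("C3", "C4"))
  expect_equal(common_average_reference(r)$data, r$data)
  r3 <- eeg_recording(matrix(2, 3, 10), 100, c("C3", "Cz", "C4"))
  expect_true(all(common_average_reference(r3)$data == 0))
})

test_that("subject filtering keeps only subjects with enough valid trials", {
  mk <- function(nt, id) generate_subject(flat_profile(), nt, 256,
                                          default_channel_labels(4),
                                          seed = nt, subject_id = id)
  cohort <- list(mk(19, "a"), mk(20, "b"), mk(35, "c"))
  expect_message(kept <- filter_subjects(cohort, 20), "excluded 1")
  expect_length(kept, 2)
  expect_identical(vapply(kept, function(r) r$subject_id, ""), c("b", "c"))
  expect_length(filter_subjects(cohort, 0), 3)
  expect_error(filter_subjects(cohort, 99), "no subject")
})

test_that("filtering and resampling commute on passband content", {
  set.seed(7)
  rate <- 2048
  t <- (0:(4 * rate - 1)) / rate
  x <- sin(2 * pi * 11 * t) + 0.5 * sin(2 * pi * 24 * t + 1)
  rec <- make_rec(x, rate)
  a <- resample_eeg(bandlimit(rec), 512)
  b <- bandlimit(resample_eeg(rec, 512))
  interior <- 200:1800
  rel <- stats::sd(a$data[1, interior] - b$data[1, interior]) /
    stats::sd(b$data[1, interior])
  expect_lt(rel, 0.02)
})

test_that("no stage reorders or renames channels", {
  ep <- generate_subject(group_preset("dysphagic"), 3, 512,
                         default_channel_labels(8), seed = 2)
  labs <- ep$labels
  out <- preprocess_subject(ep, preprocess_config(min_valid_trials = 1))
  expect_identical(out$epochs$labels, labs)
  expect_equal(dim(out$epochs$data)[1:2], dim(ep$data)[1:2])
})
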