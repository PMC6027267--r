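tone_recording <- function(freq, fs = 500, dur = 20, amp = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  eeg_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs = fs)
}

test_that("MRCP amplitude passes slow components and rejects alpha", {
  r1 <- mrcp_amplitude(tone_recording(1))[[1]]
  core <- 3000:7000
  expect_gte(max(abs(r1$values[core])), 0.7)

  r10 <- mrcp_amplitude(tone_recording(10))[[1]]
  expect_lte(max(abs(r10$values[core])), 0.1)

  z <- mrcp_amplitude(eeg_recording(matrix(0, 1, 10000), fs = 500))[[1]]
  expect_true(all(z$values == 0))
})

test_that("band power squares the band-limited signal", {
  core <- 3000:7000
  a <- band_power(tone_recording(10), "alpha")[[1]]
  expect_equal(mean(a$values[core]), 0.5, tolerance = 0.05)
  expect_true(all(a$values >= 0))

  d <- band_power(tone_recording(10), "delta")[[1]]
  expect_lte(mean(d$values[core]), 0.01)

  z <- band_power(eeg_recording(matrix(0, 1, 10000), fs = 500), "alpha")[[1]]
  expect_true(all(z$values == 0))
})

test_that("running RMS matches its closed form", {
  # hand-computed two-sample window
  rec <- eeg_recording(matrix(c(3, 4, 0, 0, 0, 0, 0, 0, 0, 0), 1), fs = 500)
  r <- rms_series(rec, window_ms = 4, prefilter = FALSE)[[1]]
  expect_equal(r$values[2], sqrt((9 + 16) / 2))
  expect_equal(r$values[1], 3)          # prefix uses the shorter window

  # constant signal reproduces its magnitude after warm-up
  recc <- eeg_recording(matrix(-2.5, 1, 1000), fs = 500)
  rc <- rms_series(recc, window_ms = 400, prefilter = FALSE)[[1]]
  expect_equal(rc$values[200:1000], rep(2.5, 801), tolerance = 1e-12)

  # 400 ms at 500 Hz is a 200-sample window: the 200th sample is the
  # first full-window value
  x <- c(rep(1, 199), rep(0, 801))
  recw <- eeg_recording(matrix(x, 1), fs = 500)
  rw <- rms_series(recw, window_ms = 400, prefilter = FALSE)[[1]]
  expect_equal(rw$values[199], 1)                    # still all-ones prefix
  expect_equal(rw$values[200], sqrt(199 / 200))      # window now holds a 0

  expect_error(rms_series(recc, window_ms = 10000, prefilter = FALSE),
               "window exceeds signal")
})

test_that("channel selection ranks the event-locked channel first", {
  set.seed(3)
  n <- 4000
  lab <- rep(0, n)
  lab[rep(seq(500, 3500, by = 1000), each = 200) + 0:199] <- 1
  mk <- function(ch, bump) feature_series("mrcp", ch,
    rnorm(n, 0, 1) + bump * (lab != 0), 500)
  series <- list(mk("Fz", 0), mk("C2", 3), mk("Cz", 0), mk("P3", 0.5))
  names(series) <- vapply(series, function(s) s$channel, "")

  picked <- select_channels(series, lab, k = 2)
  expect_identical(picked[1], "C2")

  # brute-force oracle: pooled-SD standardised mean difference
  oracle <- vapply(series, function(s) {
    g <- s$values[lab == 1]; r <- s$values[lab == 0]
    sp <- sqrt(((length(g) - 1) * var(g) + (length(r) - 1) * var(r)) /
               (length(g) + length(r) - 2))
    abs(mean(g) - mean(r)) / sp
  }, 0)
  expect_identical(picked, names(sort(-oracle))[1:2])

  # permutation invariance of the input ordering
  expect_identical(select_channels(series[c(3, 1, 4, 2)], lab, k = 2), picked)

  # overrides are returned verbatim
  expect_identical(select_channels(series, lab, override = c("FC2", "C2")),
                   c("FC2", "C2"))
  expect_identical(select_channels(series, lab, override = c("P3", "Pz")),
                   c("P3", "Pz"))
  expect_error(select_channels(series, lab, k = 9), "k exceeds")
})

test_that("the delay embedding concatenates lagged copies per channel", {
  ramp <- feature_series("rms", "C2", 0:9, fs = 1000)
  fm <- build_feature_matrix(list(ramp), lag_ms = 1, n_lags = 3)
  expect_equal(unname(fm$X[1, ]), c(2, 1, 0))
  expect_equal(fm$lag_samples, 1)

  # column j of channel c at row time t equals the series at t - jL
  two <- list(feature_series("mrcp", "FC2", sin(1:100), 500),
              feature_series("mrcp", "C2", cos(1:100), 500))
  fm2 <- build_feature_matrix(two, lag_ms = 10, n_lags = 3)   # L = 5
  expect_equal(ncol(fm2$X), 6)
  for (r in c(1, 30, 60)) {
    t0 <- fm2$row_index[r]
    expect_equal(unname(fm2$X[r, ]),
                 c(sin(t0), sin(t0 - 5), sin(t0 - 10),
                   cos(t0), cos(t0 - 5), cos(t0 - 10)))
  }

  # 250 ms at 500 Hz is 125 samples of lag
  s500 <- feature_series("mrcp", "C2", rnorm(1000), 500)
  expect_equal(build_feature_matrix(list(s500))$lag_samples, 125)

  expect_error(build_feature_matrix(list(ramp), lag_ms = 6, n_lags = 3),
               "insufficient history")
})
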