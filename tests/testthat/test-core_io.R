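test_that("session bundles round-trip through the text dialect", {
  s <- small_session()
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_identical(s2$subject_id, s$subject_id)
  expect_equal(s2$eeg$data, s$eeg$data, tolerance = 1e-9)
  expect_equal(s2$kin$shoulder_deg, s$kin$shoulder_deg, tolerance = 1e-9)
  expect_equal(s2$kin$endpoint_xy, s$kin$endpoint_xy, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(s2$labels, s$labels)
  expect_equal(s2$schedule$events, s$schedule$events, tolerance = 1e-9)

  # writing the same bundle twice gives byte-identical files
  dir2 <- withr::local_tempdir()
  write_session(s, dir2)
  for (f in list.files(dir)) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
})

test_that("incomplete or corrupt bundles are rejected", {
  s <- small_session()
  dir <- withr::local_tempdir()
  write_session(s, dir)
  file.remove(file.path(dir, "kinematics.csv"))
  expect_error(read_session(dir), "incomplete bundle")

  bad <- s
  bad$eeg$data[3, 17] <- NaN
  expect_error(write_session(bad, withr::local_tempdir()), "non-finite")

  dir3 <- withr::local_tempdir()
  write_session(s, dir3)
  meta <- yaml::read_yaml(file.path(dir3, "metadata.yaml"))
  meta$eeg$channels[[1]] <- "Oz"
  writeLines(yaml::as.yaml(meta), file.path(dir3, "metadata.yaml"))
  expect_error(read_session(dir3), "layout mismatch")
})

test_that("EDF round-trips the montage exactly and data to 16-bit scale", {
  s <- small_session()
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(s$eeg, path)
  r <- read_edf(path)
  expect_identical(r$layout$names, default_channels())
  expect_equal(r$fs, s$eeg$fs)
  # 16-bit quantisation plus header rounding: errors stay far below
  # one part in five thousand of the data range
  span <- diff(range(s$eeg$data))
  expect_lt(max(abs(r$data - s$eeg$data)), span / 5000)
})

test_that("label track follows detector-marked movement windows", {
  kin <- ramp_kin()
  sched <- cue_schedule(data.frame(time_s = 10, class = 1))
  lab <- label_track_from_schedule(sched, kin, n_samples = 7000, fs = 500)
  # movement 10.4-12.4 s at 500 Hz: zero-based samples 5200..6199
  expect_identical(which(lab == 1), 5201:6200)
  expect_true(all(lab[-(5201:6200)] == 0))

  expect_identical(label_track_from_schedule(cue_schedule(data.frame()),
                                             kin, 7000, 500),
                   numeric(7000))
  late <- cue_schedule(data.frame(time_s = 20, class = -1))
  expect_error(label_track_from_schedule(late, kin, 7000, 500),
               "schedule overrun")
})

test_that("protocol sessions yield one labelled span per cue, balanced", {
  s <- full_session()
  r <- rle(s$labels)
  spans <- r$values[r$values != 0]
  expect_length(spans, 20)
  expect_equal(sum(spans == 1), 10)
  expect_equal(sum(spans == -1), 10)
  expect_true(all(s$labels %in% c(-1, 0, 1)))
  # initial rest lead is silent
  expect_true(all(s$labels[1:(10 * 500)] == 0))
})

test_that("kinematics resampling preserves duration within one period", {
  kin <- ramp_kin(fs = 120, total_s = 14)
  rs <- resample_kinematics(kin, 500)
  expect_lt(abs(length(rs$shoulder_deg) / 500 -
                length(kin$shoulder_deg) / 120), 1 / 120)
  expect_equal(rs$fs, 500)
  # endpoints preserved
  expect_equal(rs$shoulder_deg[1], kin$shoulder_deg[1], tolerance = 1e-6)
  expect_equal(max(rs$shoulder_deg), 90, tolerance = 0.5)
})

test_that("constructors enforce the core invariants", {
  expect_error(channel_layout(c("Cz", "Cz")), "unique")
  expect_error(eeg_recording(matrix(1, 2, 10), fs = -1), "fs")
  expect_error(eeg_recording(matrix(c(1, NA), 2, 10)), "non-finite")
  expect_error(cue_schedule(data.frame(time_s = c(2, 1), class = c(1, 1))),
               "clock error")
  expect_error(cue_schedule(data.frame(time_s = 1, class = 2)), "class code")
  expect_error(kinematics_trace(100, c(0, 200), c(0, 0),
                                matrix(0, 2, 2)), "0, 180")
})
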