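# hand-built session: one reaching movement, 10.4-12.4 s, at 500 Hz
reach_session <- function() {
  fixture("reach_session", {
    fs <- 500
    n <- 7000
    kin <- ramp_kin()
    # reaching elbow/endpoint templates driven by the ramp
    sched <- cue_schedule(data.frame(time_s = 10, class = -1))
    eeg <- eeg_recording(matrix(0, 16, n), fs = fs)
    labels <- label_track_from_schedule(sched, kin, n, fs)
    session_bundle("SX", eeg, sched, kin, labels)
  })
}

test_that("the motion database pools labelled samples with history", {
  s <- reach_session()
  db <- build_motion_database(s, rest_margin_ms = 0)
  expect_equal(sum(db$records$class == -1), 1000)   # 2 s at 500 Hz
  expect_true(all(db$records$subject == "SX"))
  # shoulder history comes strictly from current/past samples
  i <- which(db$records$class == -1)[500]
  expect_gte(db$records$s0[i], db$records$s250[i])
  expect_gte(db$records$s250[i], db$records$s500[i])

  expect_equal(nrow(build_motion_database(list())$records), 0)
})

test_that("lifting records keep the elbow at full extension", {
  sess <- fixture("motion_sessions",
    generate_study(3, synthetic_config(n_trials = 8), seed = 11))
  db <- build_motion_database(sess, stride = 10L)
  lift <- db$records[db$records$class == 1, ]
  expect_gt(nrow(lift), 100)
  expect_lt(max(abs(lift$elbow - 175)), 2.5)
})

test_that("leave-one-subject-out training audits the exclusion", {
  sess <- fixture("motion_sessions",
    generate_study(3, synthetic_config(n_trials = 8), seed = 11))
  db <- fixture("motion_db", build_motion_database(sess, stride = 10L))
  est <- fixture("elbow_est",
    train_estimator(db, "elbow", exclude_subject = "S1", epochs = 1500,
                    seed = 1))
  expect_false("S1" %in% est$train_subjects)
  expect_setequal(est$train_subjects, c("S2", "S3"))

  only <- build_motion_database(sess["S1"], stride = 10L)
  expect_error(train_estimator(only, "elbow", exclude_subject = "S1"),
               "empty training set")
})

test_that("duplicated records leave the full-batch fit unchanged", {
  sess <- fixture("motion_sessions",
    generate_study(3, synthetic_config(n_trials = 8), seed = 11))
  db <- fixture("motion_db", build_motion_database(sess, stride = 10L))
  db2 <- db
  db2$records <- rbind(db$records, db$records)
  e1 <- train_estimator(db, "elbow", exclude_subject = "S1", epochs = 200,
                        seed = 3)
  e2 <- train_estimator(db2, "elbow", exclude_subject = "S1", epochs = 200,
                        seed = 3)
  expect_identical(e1$fit$W1, e2$fit$W1)
  expect_identical(e1$fit$W2, e2$fit$W2)
})

test_that("estimates respect the learned motion relationships", {
  sess <- fixture("motion_sessions",
    generate_study(3, synthetic_config(n_trials = 8), seed = 11))
  db <- fixture("motion_db", build_motion_database(sess, stride = 10L))
  est <- fixture("elbow_est",
    train_estimator(db, "elbow", exclude_subject = "S1", epochs = 1500,
                    seed = 1))
  # lifting: elbow stays at full extension whatever the shoulder does
  expect_lt(abs(estimate(est, 1, 45, 40, 35) - 175), 5)
  # reaching at the dip region: well below the extended start
  expect_lt(estimate(est, -1, 20, 15, 10), 160)
  # rest with stationary shoulder history is time-invariant
  a <- estimate(est, 0, 5, 5, 5)
  b <- estimate(est, 0, 5, 5, 5)
  expect_identical(a, b)

  ep <- fixture("endpoint_est",
    train_estimator(db, "endpoint", exclude_subject = "S1", epochs = 1500,
                    seed = 1))
  # reaching endpoint sits on its plateau once the shoulder passes 30 deg
  p40 <- estimate(ep, -1, 40, 38, 36)
  p80 <- estimate(ep, -1, 80, 78, 76)
  expect_lt(abs(p40[1] - p80[1]), 0.05 * max(abs(p80[1]), 0.1))

  expect_error(estimate(est, 2, 10, 10, 10), "class_code")
  expect_warning(estimate(est, 0, 500, 500, 500), "clipped")
})
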