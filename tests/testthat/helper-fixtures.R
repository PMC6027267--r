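# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# short protocol session for feature-level tests (8 trials, ~54 s)
small_session <- function() fixture("small_session",
  generate_session(synthetic_config(n_trials = 8), seed = 42,
                   subject_id = "S1"))

# full-protocol session (20 trials) for end-to-end checks
full_session <- function() fixture("full_session",
  generate_session(synthetic_config(), seed = 1, subject_id = "S1"))

# ramp kinematics: still until `on_s`, constant-rate rise to `deg` over
# `dur_s`, then hold
ramp_kin <- function(fs = 500, total_s = 14, on_s = 10.4, dur_s = 2,
                     deg = 90) {
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  th <- pmin(pmax((t - on_s) / dur_s, 0), 1) * deg
  kinematics_trace(fs, th, rep(175, n),
                   cbind(rep(0, n), rep(-0.7, n)))
}

# well-separated three-cluster fixture in 2-D
separable_clusters <- function(n_per = 120, sd = 0.5, seed = 7) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2, -4, sd), n_per, 2),
             matrix(rnorm(n_per * 2, 0, sd), n_per, 2),
             matrix(rnorm(n_per * 2, 4, sd), n_per, 2))
  list(X = X, y = rep(c(-1, 0, 1), each = n_per))
}
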