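#' Synthetic session configuration
#'
#' Parameters of the synthetic session generator. The defaults encode the
#' assumed study conditions: a 10 s initial rest, 20 cued trials (10 arm
#' lifting, 10 hand reaching, random order) separated by gaps drawn from
#' {5, 6} s, EEG at 500 Hz on the 16-channel montage, kinematics captured
#' at 120 Hz. Electrophysiological signatures: an event-locked slow
#' negative potential over FC2/C2 rising through the 1.5 s before
#' movement onset (peak amplitude -8 uV lifting, -12 uV reaching, with a
#' class-specific lateral spread over the two channels), an ongoing ~10 Hz
#' alpha rhythm on P3/Pz attenuated to a 0.4 amplitude factor during
#' movement, and 1/f background noise on all channels. Kinematic
#' templates: minimum-jerk shoulder excursion to 90 degrees; elbow pinned
#' near full extension (175 deg) for lifting; for reaching an elbow
#' dip-then-extend curve (fast initial flexion, minimum near 20 deg of
#' shoulder travel, re-extension) and a hand endpoint that rises to its
#' plateau within the first 20 degrees of shoulder motion and stays there.
#'
#' @param n_trials Number of cued trials (even; default 20).
#' @param rest_lead_s Initial rest in seconds (default 10).
#' @param gap_choices_s Candidate inter-cue gaps in seconds (default 5, 6).
#' @param fs EEG sampling rate in Hz (default 500).
#' @param kin_fs Motion-capture rate in Hz (default 120).
#' @param mrcp_amp_uv Named peak amplitudes (uV) of the slow potential,
#'   `c(lifting = -8, reaching = -12)`.
#' @param mrcp_spread Per-class channel weights on FC2/C2.
#' @param mrcp_rise_s Pre-onset rise time of the slow potential (s).
#' @param alpha_base_uv Alpha oscillation amplitude on P3/Pz (uV).
#' @param alpha_freq_hz Alpha frequency (default 10).
#' @param alpha_attenuation Amplitude factor during movement (default 0.4).
#' @param alpha_spread Per-class relative attenuation weights on P3/Pz;
#'   the slight class asymmetry emulates the distinct parietal
#'   topographies of the two movements, which is what makes the alpha
#'   feature class-informative rather than a pure movement detector.
#' @param noise_rms_uv Per-channel background noise RMS (default 6).
#' @param noise_exponent Spectral exponent of the 1/f^a background
#'   (default 1).
#' @param movement_dur_s Outbound movement duration per class (s); the
#'   return mirrors it.
#' @param reaction_s Cue-to-onset reaction delay (default 0.4 s).
#' @param shoulder_max_deg Shoulder excursion (default 90).
#' @param elbow_extended_deg Fully extended elbow angle (default 175).
#' @param elbow_dip_deg Depth of the reaching elbow dip (default 70).
#' @param dip_shoulder_deg Shoulder angle of maximal dip / endpoint
#'   plateau onset (default 20).
#' @param arm_length_m Extended-arm length for the lifting endpoint arc.
#' @param endpoint_target_xy Reaching endpoint plateau (x, y) in metres,
#'   shoulder-centred.
#' @param angle_noise_sd_deg Gaussian noise on the angle series.
#' @param endpoint_noise_sd_m Gaussian noise on the endpoint series.
#' @param difficulty Scales signature strength: multiplies the slow
#'   potential amplitudes and the alpha-attenuation contrast. 1 = default
#'   conditions, 0 = a null world with no class information in the EEG.
#' @param seed Default generator seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_trials = 20, rest_lead_s = 10,
                             gap_choices_s = c(5, 6), fs = 500,
                             kin_fs = 120,
                             mrcp_amp_uv = c(lifting = -8, reaching = -12),
                             mrcp_spread = list(
                               lifting = c(FC2 = 0.6, C2 = 1.0),
                               reaching = c(FC2 = 1.0, C2 = 0.6)),
                             mrcp_rise_s = 1.5,
                             alpha_base_uv = 10, alpha_freq_hz = 10,
                             alpha_attenuation = 0.4,
                             alpha_spread = list(
                               lifting = c(P3 = 0.7, Pz = 1.0),
                               reaching = c(P3 = 1.0, Pz = 0.7)),
                             noise_rms_uv = 1.5, noise_exponent = 1,
                             movement_dur_s = c(lifting = 2, reaching = 2),
                             reaction_s = 0.4,
                             shoulder_max_deg = 90,
                             elbow_extended_deg = 175,
                             elbow_dip_deg = 70, dip_shoulder_deg = 20,
                             arm_length_m = 0.7,
                             endpoint_target_xy = c(0.6, 0),
                             angle_noise_sd_deg = 0.5,
                             endpoint_noise_sd_m = 0.002,
                             difficulty = 1, seed = 1) {
  cfg <- list(n_trials = n_trials, rest_lead_s = rest_lead_s,
              gap_choices_s = gap_choices_s, fs = fs, kin_fs = kin_fs,
              mrcp_amp_uv = mrcp_amp_uv, mrcp_spread = mrcp_spread,
              mrcp_rise_s = mrcp_rise_s, alpha_base_uv = alpha_base_uv,
              alpha_freq_hz = alpha_freq_hz,
              alpha_attenuation = alpha_attenuation,
              alpha_spread = alpha_spread,
              noise_rms_uv = noise_rms_uv, noise_exponent = noise_exponent,
              movement_dur_s = movement_dur_s, reaction_s = reaction_s,
              shoulder_max_deg = shoulder_max_deg,
              elbow_extended_deg = elbow_extended_deg,
              elbow_dip_deg = elbow_dip_deg,
              dip_shoulder_deg = dip_shoulder_deg,
              arm_length_m = arm_length_m,
              endpoint_target_xy = endpoint_target_xy,
              angle_noise_sd_deg = angle_noise_sd_deg,
              endpoint_noise_sd_m = endpoint_noise_sd_m,
              difficulty = difficulty, seed = seed)
  if (!all(is.finite(unlist(cfg[c("mrcp_amp_uv", "alpha_base_uv",
                                  "noise_rms_uv")]))))
    stop("amplitudes must be finite")
  structure(cfg, class = "synthetic_config")
}

#' Randomised cue schedule
#'
#' Exactly half the cues per class, in random order, with inter-cue gaps
#' drawn uniformly from `gap_choices_s`, after the initial rest.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return A [cue_schedule()].
#' @export
generate_schedule <- function(cfg = synthetic_config(), seed = cfg$seed) {
  if (cfg$n_trials %% 2 != 0) stop("unbalanced schedule")
  with_seed(seed, {
    classes <- sample(rep(c(1, -1), each = cfg$n_trials / 2))
    gaps <- sample(cfg$gap_choices_s, cfg$n_trials - 1, replace = TRUE)
    times <- cfg$rest_lead_s + c(0, cumsum(gaps))
    cue_schedule(data.frame(time_s = times, class = classes),
                 rest_lead_s = cfg$rest_lead_s)
  })
}

session_duration_s <- function(schedule, cfg) {
  if (nrow(schedule$events) == 0) return(cfg$rest_lead_s)
  max(schedule$events$time_s) + max(cfg$gap_choices_s)
}

min_jerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

smoothstep <- function(u) {u <- pmin(pmax(u, 0), 1); 3 * u^2 - 2 * u^3}

# elbow flexion dip for reaching: minimum (= extended - dip) at
# theta = dip_shoulder_deg, re-extending towards larger shoulder angles
elbow_reach_template <- function(theta, cfg) {
  u <- theta / cfg$dip_shoulder_deg
  cfg$elbow_extended_deg - cfg$elbow_dip_deg * (u * exp(1 - u))^2
}

endpoint_rest_xy <- function(cfg) c(0, -cfg$arm_length_m)

endpoint_reach_template <- function(theta, cfg) {
  s <- smoothstep(theta / cfg$dip_shoulder_deg)
  r0 <- endpoint_rest_xy(cfg)
  cbind(r0[1] + (cfg$endpoint_target_xy[1] - r0[1]) * s,
        r0[2] + (cfg$endpoint_target_xy[2] - r0[2]) * s)
}

#' Synthetic limb kinematics for a schedule
#'
#' Shoulder, elbow and hand-endpoint series at the motion-capture rate.
#' Each trial is a minimum-jerk shoulder excursion to
#' `shoulder_max_deg` starting `reaction_s` after the cue, with the
#' return phase mirroring the outbound one. Lifting keeps the elbow at
#' full extension with the endpoint on the extended-arm arc; reaching
#' follows the dip-then-extend elbow template and the endpoint
#' plateau-by-20-degrees template (both are functions of the shoulder
#' angle, so the return retraces them).
#'
#' @param schedule A [cue_schedule()].
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return A [kinematics_trace()] at `cfg$kin_fs`.
#' @export
generate_kinematics <- function(schedule, cfg = synthetic_config(),
                                seed = cfg$seed) {
  dur_total <- session_duration_s(schedule, cfg)
  n <- as.integer(round(dur_total * cfg$kin_fs))
  t <- (seq_len(n) - 1) / cfg$kin_fs
  theta <- numeric(n)
  elbow <- rep(cfg$elbow_extended_deg, n)
  ep <- matrix(rep(endpoint_rest_xy(cfg), each = n), n, 2)
  ev <- schedule$events
  for (i in seq_len(nrow(ev))) {
    cls <- if (ev$class[i] == 1) "lifting" else "reaching"
    onset <- ev$time_s[i] + cfg$reaction_s
    dur <- unname(cfg$movement_dur_s[cls])
    inwin <- t >= onset & t < onset + 2 * dur
    u <- (t[inwin] - onset) / dur
    phase <- ifelse(u <= 1, u, 2 - u)
    th <- cfg$shoulder_max_deg * min_jerk(phase)
    theta[inwin] <- th
    if (cls == "lifting") {
      ep[inwin, 1] <- cfg$arm_length_m * sinpi(th / 180)
      ep[inwin, 2] <- -cfg$arm_length_m * cospi(th / 180)
    } else {
      elbow[inwin] <- elbow_reach_template(th, cfg)
      ep[inwin, ] <- endpoint_reach_template(th, cfg)
    }
  }
  # marker jitter: Gaussian amplitude but band-limited (~8 Hz), since
  # white angle noise at the capture rate would imply implausible
  # instantaneous velocities
  jitter <- function(sd) {
    if (sd <= 0 || n < 4) return(numeric(n))
    k <- max(2L, as.integer(round(cfg$kin_fs / 8)))
    y <- stats::filter(stats::rnorm(n), rep(1 / k, k), circular = TRUE)
    as.numeric(y) * sd / stats::sd(y)
  }
  with_seed(seed, {
    theta <- theta + jitter(cfg$angle_noise_sd_deg)
    elbow <- elbow + jitter(cfg$angle_noise_sd_deg)
    ep <- ep + cbind(jitter(cfg$endpoint_noise_sd_m),
                     jitter(cfg$endpoint_noise_sd_m))
  })
  kinematics_trace(cfg$kin_fs, pmin(pmax(theta, 0), 180),
                   pmin(pmax(elbow, 0), 180), ep)
}

# one channel of 1/f^a noise via spectral shaping, scaled to target RMS
pink_noise <- function(n, fs, exponent, rms) {
  w <- stats::rnorm(n)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)                    # two-sided frequency axis
  scale <- pmax(f, 0.1)^(-exponent / 2)
  scale[1] <- 0                           # no DC
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Synthetic EEG for a schedule
#'
#' All 16 channels carry independent 1/f background noise. FC2 and C2
#' additionally carry the event-locked slow negative potential (half-
#' cosine rise over the `mrcp_rise_s` before movement onset, peak at
#' onset, half-cosine decay over the movement), with class-specific peak
#' amplitude and lateral spread. P3 and Pz carry the alpha rhythm,
#' attenuated towards `alpha_attenuation` during movement.
#'
#' @param schedule A [cue_schedule()].
#' @param kin The matching [kinematics_trace()] (fixes the session
#'   length).
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return An [eeg_recording()] at `cfg$fs` on the default montage.
#' @export
generate_eeg <- function(schedule, kin, cfg = synthetic_config(),
                         seed = cfg$seed) {
  dur_total <- length(kin$shoulder_deg) / kin$fs
  n <- as.integer(round(dur_total * cfg$fs))
  t <- (seq_len(n) - 1) / cfg$fs
  chans <- default_channels()
  data <- with_seed(seed, {
    m <- matrix(0, length(chans), n)
    for (i in seq_along(chans))
      if (cfg$noise_rms_uv > 0)
        m[i, ] <- pink_noise(n, cfg$fs, cfg$noise_exponent, cfg$noise_rms_uv)
    m
  })
  rownames(data) <- chans
  ev <- schedule$events
  # event-locked slow potential on FC2/C2; per-channel movement
  # envelopes (class-weighted) for the alpha attenuation on P3/Pz
  mrcp <- list(FC2 = numeric(n), C2 = numeric(n))
  alpha_env <- list(P3 = numeric(n), Pz = numeric(n))
  ramp <- 0.25
  for (i in seq_len(nrow(ev))) {
    cls <- if (ev$class[i] == 1) "lifting" else "reaching"
    onset <- ev$time_s[i] + cfg$reaction_s
    dur <- unname(cfg$movement_dur_s[cls])
    amp <- unname(cfg$mrcp_amp_uv[cls]) * cfg$difficulty
    rise <- t >= onset - cfg$mrcp_rise_s & t < onset
    decay <- t >= onset & t < onset + dur
    bump <- numeric(n)
    bump[rise] <- (1 - cospi((t[rise] - onset + cfg$mrcp_rise_s) /
                               cfg$mrcp_rise_s)) / 2
    bump[decay] <- (1 + cospi((t[decay] - onset) / dur)) / 2
    for (ch in c("FC2", "C2"))
      mrcp[[ch]] <- mrcp[[ch]] + amp * cfg$mrcp_spread[[cls]][[ch]] * bump
    m0 <- onset; m1 <- onset + 2 * dur
    core <- t >= m0 & t < m1
    env <- numeric(n)
    env[core] <- pmin(1, pmin(t[core] - m0, m1 - t[core]) / ramp)
    for (ch in c("P3", "Pz"))
      alpha_env[[ch]] <- pmax(alpha_env[[ch]],
                              cfg$alpha_spread[[cls]][[ch]] * env)
  }
  data["FC2", ] <- data["FC2", ] + mrcp$FC2
  data["C2", ] <- data["C2", ] + mrcp$C2
  contrast <- (1 - cfg$alpha_attenuation) * cfg$difficulty
  phases <- with_seed(seed + 31L, stats::runif(2, 0, 2 * pi))
  for (j in 1:2) {
    ch <- c("P3", "Pz")[j]
    gain <- 1 - contrast * alpha_env[[ch]]
    data[ch, ] <- data[ch, ] + cfg$alpha_base_uv * gain *
      sin(2 * pi * cfg$alpha_freq_hz * t + phases[j])
  }
  eeg_recording(data, fs = cfg$fs)
}

#' Generate a complete synthetic session
#'
#' Draws a schedule, kinematics and EEG, aligns the kinematics to the EEG
#' clock, derives per-sample labels from the cue schedule and the limb
#' motion detector, and returns the assembled [session_bundle()].
#' Bit-reproducible for a fixed `(cfg, seed)`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Master seed; sub-streams for schedule, kinematics and EEG
#'   are derived from it.
#' @param subject_id Subject identifier (default "S1").
#' @return A [session_bundle()].
#' @export
generate_session <- function(cfg = synthetic_config(), seed = cfg$seed,
                             subject_id = "S1") {
  seed <- as.integer(seed)
  schedule <- generate_schedule(cfg, seed)
  kin <- generate_kinematics(schedule, cfg, seed + 1L)
  eeg <- generate_eeg(schedule, kin, cfg, seed + 2L)
  kin_rs <- resample_kinematics(kin, cfg$fs, n_out = ncol(eeg$data))
  labels <- label_track_from_schedule(schedule, kin_rs,
                                      n_samples = ncol(eeg$data),
                                      fs = cfg$fs)
  session_bundle(subject_id, eeg, schedule, kin_rs, labels)
}

#' Generate a multi-subject study
#'
#' One session per subject, each from its own seed sub-stream.
#'
#' @param n_subjects Number of subjects.
#' @param cfg A [synthetic_config()].
#' @param seed Master seed.
#' @return List of [session_bundle()]s named `S1..Sn`.
#' @export
generate_study <- function(n_subjects = 5, cfg = synthetic_config(),
                           seed = cfg$seed) {
  ids <- paste0("S", seq_len(n_subjects))
  stats::setNames(lapply(seq_len(n_subjects), function(i)
    generate_session(cfg, seed = as.integer(seed) + 1000L * i,
                     subject_id = ids[i])), ids)
}
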