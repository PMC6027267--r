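#' Pool per-sample motion records from labelled sessions
#'
#' Builds the healthy-subject motion database that stage two trains on:
#' one record per (strided) EEG-rate sample inside each labelled movement
#' span, holding the class code, the shoulder-angle history at lags 0,
#' 250 and 500 ms, and the targets (elbow angle, hand endpoint). A rest
#' margin around each span contributes class-0 records so the estimators
#' also see the resting posture.
#'
#' @param sessions List of [session_bundle()] objects (or one bundle).
#' @param lags_ms Shoulder-history lags in ms (default `c(0, 250, 500)`).
#' @param rest_margin_ms Rest margin kept on each side of a movement span
#'   (default 250 ms).
#' @param stride Keep every `stride`-th sample (default 1 = all).
#' @return A `motion_database` wrapping a data frame with columns
#'   `subject`, `class`, `s0`, `s250`, `s500` (degrees), `elbow` (degrees),
#'   `x`, `y` (metres).
#' @export
build_motion_database <- function(sessions, lags_ms = c(0, 250, 500),
                                  rest_margin_ms = 250, stride = 1L) {
  if (inherits(sessions, "session_bundle")) sessions <- list(sessions)
  recs <- list()
  for (s in sessions) {
    if (is.null(s$kin)) {
      warning("session ", s$subject_id, " has no kinematics; skipped")
      next
    }
    fs <- s$eeg$fs
    lag_n <- as.integer(round(lags_ms * fs / 1000))
    margin <- as.integer(round(rest_margin_ms * fs / 1000))
    lab <- s$labels
    n <- length(lab)
    keep <- logical(n)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] == 0) next
      keep[max(1L, starts[i] - margin):min(n, ends[i] + margin)] <- TRUE
    }
    idx <- which(keep)
    idx <- idx[idx > max(lag_n)]
    if (stride > 1L) idx <- idx[seq(1L, length(idx), by = as.integer(stride))]
    if (!length(idx)) next
    sh <- s$kin$shoulder_deg
    recs[[length(recs) + 1L]] <- data.frame(
      subject = s$subject_id,
      class = lab[idx],
      s0 = sh[idx - lag_n[1]],
      s250 = sh[idx - lag_n[2]],
      s500 = sh[idx - lag_n[3]],
      elbow = s$kin$elbow_deg[idx],
      x = s$kin$endpoint_xy[idx, 1],
      y = s$kin$endpoint_xy[idx, 2])
  }
  df <- if (length(recs)) do.call(rbind, recs)
        else data.frame(subject = character(0), class = numeric(0),
                        s0 = numeric(0), s250 = numeric(0), s500 = numeric(0),
                        elbow = numeric(0), x = numeric(0), y = numeric(0))
  structure(list(records = df), class = "motion_database")
}

#' @export
print.motion_database <- function(x, ...) {
  cat("<motion_database> ", nrow(x$records), " records from ",
      length(unique(x$records$subject)), " subject(s)\n", sep = "")
  invisible(x)
}

#' Train a distal-motion estimator, leave-one-subject-out
#'
#' A 10-hidden-unit sigmoid network maps (class code, shoulder angle at
#' 0/250/500 ms) to either the elbow flexion/extension angle or the hand
#' endpoint (x, y emitted jointly by one network). The excluded subject
#' plays the amputee: none of their records enter training, so the fit
#' expresses only the pooled shoulder-to-distal relationship of the
#' remaining subjects. Inputs are min-max scaled to the unit interval
#' with training
#' statistics; targets are standardised internally but predictions return
#' in native units.
#'
#' @param db A [build_motion_database()] result.
#' @param target `"elbow"` (degrees) or `"endpoint"` (metres, 2 outputs).
#' @param exclude_subject Subject id held out of training (optional).
#' @param n_hidden Hidden units (default 10).
#' @param lr,epochs,tol,seed Training controls, as in [train_mlp()].
#' @return A `motion_estimator`.
#' @export
train_estimator <- function(db, target = c("elbow", "endpoint"),
                            exclude_subject = NULL, n_hidden = 10,
                            lr = 0.01, epochs = 2000, tol = 1e-6, seed = 1) {
  target <- match.arg(target)
  stopifnot(inherits(db, "motion_database"))
  df <- db$records
  if (!is.null(exclude_subject)) df <- df[df$subject != exclude_subject, ]
  if (nrow(df) == 0) stop("empty training set")
  if (length(unique(df$subject)) < 2)
    stop("need at least two training subjects")
  X <- as.matrix(df[, c("class", "s0", "s250", "s500")])
  Y <- if (target == "elbow") as.matrix(df[, "elbow", drop = FALSE])
       else as.matrix(df[, c("x", "y")])
  in_min <- apply(X, 2, min); in_max <- apply(X, 2, max)
  span <- pmax(in_max - in_min, 1e-9)
  Xs <- sweep(sweep(X, 2, in_min), 2, span, "/")
  y_mu <- colMeans(Y)
  # population scale, so duplicating the record set leaves the fit intact
  y_sd <- pmax(sqrt(colMeans(sweep(Y, 2, y_mu)^2)), 1e-9)
  Ys <- sweep(sweep(Y, 2, y_mu), 2, y_sd, "/")
  fit <- mlp_fit(Xs, Ys, n_hidden = n_hidden, out_act = "linear",
                 lr = lr, epochs = epochs, tol = tol, seed = seed,
                 optimizer = "rprop")
  structure(list(target = target, fit = fit,
                 in_min = in_min, in_max = in_max,
                 y_mean = y_mu, y_sd = y_sd,
                 y_range = apply(Y, 2, range),
                 excluded_subject = exclude_subject,
                 train_subjects = unique(df$subject),
                 n_hidden = n_hidden, seed = seed),
            class = "motion_estimator")
}

#' @export
print.motion_estimator <- function(x, ...) {
  cat("<motion_estimator> target ", x$target, ", ", x$n_hidden,
      " hidden units, trained on subjects ",
      paste(x$train_subjects, collapse = ","),
      if (!is.null(x$excluded_subject))
        paste0(" (excluding ", x$excluded_subject, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Estimate distal motion from class and shoulder history
#'
#' @param est A [train_estimator()] result.
#' @param class_code Decoded intention in `{-1, 0, +1}` (vectorised).
#' @param shoulder_now,shoulder_250,shoulder_500 Shoulder angle in degrees
#'   at lags 0, 250 and 500 ms.
#' @return For `target = "elbow"` a numeric vector of elbow angles in
#'   degrees; for `"endpoint"` a two-column matrix (x, y) in metres.
#'   Outputs are clipped to the training target range plus a 10% margin;
#'   shoulder inputs outside the training range are clipped with a
#'   warning.
#' @export
estimate <- function(est, class_code, shoulder_now, shoulder_250,
                     shoulder_500) {
  stopifnot(inherits(est, "motion_estimator"))
  if (!all(class_code %in% c(-1, 0, 1)))
    stop("class_code must be in {-1, 0, +1}")
  X <- cbind(class = class_code, s0 = shoulder_now,
             s250 = shoulder_250, s500 = shoulder_500)
  lo <- matrix(est$in_min, nrow(X), 4, byrow = TRUE)
  hi <- matrix(est$in_max, nrow(X), 4, byrow = TRUE)
  if (any(X < lo - 1e-9) || any(X > hi + 1e-9)) {
    warning("input outside training range; clipped")
    X <- pmin(pmax(X, lo), hi)
  }
  span <- pmax(est$in_max - est$in_min, 1e-9)
  Xs <- sweep(sweep(X, 2, est$in_min), 2, span, "/")
  Ys <- mlp_predict(est$fit, Xs)
  Y <- sweep(sweep(Ys, 2, est$y_sd, "*"), 2, est$y_mean, "+")
  for (j in seq_len(ncol(Y))) {
    r <- est$y_range[, j]
    pad <- 0.1 * (r[2] - r[1])
    Y[, j] <- pmin(pmax(Y[, j], r[1] - pad), r[2] + pad)
  }
  if (est$target == "elbow") as.numeric(Y)
  else {colnames(Y) <- c("x", "y"); Y}
}
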