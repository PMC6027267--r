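#' Train the neural-network intention classifier
#'
#' A single-hidden-layer sigmoid network trained by full-batch error
#' backpropagation to regress the class code: targets are `+1` for arm
#' lifting, `-1` for hand reaching, `0` for rest, and the output unit is a
#' sigmoid rescaled to `(-1, 1)`. The hidden layer has 30 units for a
#' single feature family and 80 when all four families are combined.
#' Features are z-scored with statistics of the training rows; the scaler
#' travels with the model.
#'
#' @param X A [build_feature_matrix()] result or plain numeric matrix
#'   (training rows only).
#' @param y Class series in `{-1, 0, +1}`, one per row.
#' @param n_hidden Hidden units; default 30, or 80 if `X` carries more
#'   than one feature kind.
#' @param lr Initial learning rate (default 0.01).
#' @param epochs Maximum training epochs (default 2000); training stops
#'   early once the loss improvement falls below `tol`.
#' @param tol Early-stopping threshold on the MSE improvement.
#' @param seed Integer seed for the weight initialisation.
#' @return An `intention_model` (type `"mlp"`).
#' @export
train_mlp <- function(X, y, n_hidden = NULL, lr = 0.01, epochs = 2000,
                      tol = 1e-6, seed = 1) {
  fm <- if (inherits(X, "feature_matrix")) X else NULL
  Xm <- if (is.null(fm)) as.matrix(X) else fm$X
  y <- as.numeric(y)
  stopifnot(nrow(Xm) == length(y))
  if (!all(y %in% c(-1, 0, 1))) stop("labels must be in {-1, 0, +1}")
  if (length(unique(y)) < 2) stop("degenerate labels")
  if (is.null(n_hidden))
    n_hidden <- if (!is.null(fm) && length(fm$kinds) > 1) 80L else 30L
  sc <- scaler_fit(Xm)
  fit <- mlp_fit(scaler_apply(sc, Xm), matrix(y, ncol = 1),
                 n_hidden = n_hidden, out_act = "tanh_unit",
                 lr = lr, epochs = epochs, tol = tol, seed = seed)
  structure(list(type = "mlp", fit = fit, scaler = sc,
                 n_inputs = ncol(Xm), n_hidden = n_hidden,
                 train_n = nrow(Xm), seed = seed,
                 feature_kinds = if (is.null(fm)) NA_character_ else fm$kinds),
            class = "intention_model")
}

#' Continuous classifier output
#'
#' The raw network output in `(-1, 1)`; values near `+1` indicate arm
#' lifting, near `-1` hand reaching, near `0` rest. Use [discretize()] to
#' map to class codes.
#'
#' @param m An `intention_model` of type `"mlp"`.
#' @param X Feature matrix (or `feature_matrix`) with the model's column
#'   count.
#' @return Numeric series in `(-1, 1)`.
#' @export
predict_continuous <- function(m, X) {
  stopifnot(inherits(m, "intention_model"))
  if (m$type != "mlp") stop("continuous output is only defined for MLP models")
  Xm <- if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
  if (ncol(Xm) != m$n_inputs)
    stop("dimension mismatch: model expects ", m$n_inputs, " inputs")
  as.numeric(mlp_predict(m$fit, scaler_apply(m$scaler, Xm)))
}

#' Threshold continuous output into class codes
#'
#' Values below the lower threshold become reaching (`-1`), above the
#' upper threshold lifting (`+1`), everything else rest (`0`). Values
#' exactly on a threshold tie to rest.
#'
#' @param values Numeric series in `[-1, 1]`.
#' @param thresholds Ordered pair, default `c(-0.5, 0.5)`.
#' @return Class series in `{-1, 0, +1}`.
#' @export
discretize <- function(values, thresholds = c(-0.5, 0.5)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  out <- numeric(length(values))
  out[values < thresholds[1]] <- -1
  out[values > thresholds[2]] <- 1
  out
}

knn_metrics <- c("euclidean", "cityblock", "cosine")

knn_distance <- function(A, B, metric) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (metric == "euclidean") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  } else if (metric == "cityblock") {
    D <- matrix(0, nrow(A), nrow(B))
    for (j in seq_len(ncol(A)))
      D <- D + abs(outer(A[, j], B[, j], "-"))
    D
  } else if (metric == "cosine") {
    na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
    na[na == 0] <- Inf; nb[nb == 0] <- Inf
    1 - tcrossprod(A, B) / outer(na, nb)
  } else stop("unknown metric: ", metric)
}

# tie-break shared by both vote rules: rest wins ties, then the smallest
# class code
knn_pick <- function(scores) {
  best <- names(scores)[scores >= max(scores) - 1e-12]
  if ("0" %in% best) 0 else min(as.numeric(best))
}

knn_vote <- function(D, train_y, k, vote) {
  apply(D, 1, function(drow) {
    nn <- order(drow)[seq_len(k)]
    cls <- train_y[nn]
    scores <- if (vote == "majority") {
      tapply(rep(1, k), factor(cls, levels = c(-1, 0, 1)), sum)
    } else {
      w <- 1 / (1 + drow[nn])
      tapply(w, factor(cls, levels = c(-1, 0, 1)), sum)
    }
    scores[is.na(scores)] <- 0
    knn_pick(scores)
  })
}

#' Train the k-nearest-neighbour intention classifier
#'
#' Grid search over the neighbour count, distance metric and vote rule,
#' selecting the configuration that minimises 5-fold cross-validated
#' misclassification on the training rows (folds are contiguous blocks,
#' keeping temporally adjacent -- and hence correlated -- rows together).
#' Ties prefer the smaller `k`, then the earlier metric, then the earlier
#' vote rule. Two vote rules are available: plain majority among the `k`
#' nearest training rows, and a similarity-weighted vote with
#' `Sim = 1 / (1 + distance)`.
#'
#' @param X Feature matrix (or `feature_matrix`), training rows.
#' @param y Class series in `{-1, 0, +1}`.
#' @param k_grid Candidate neighbour counts (default odd 1..25).
#' @param metric_grid Candidate metrics among
#'   `"euclidean"`, `"cityblock"`, `"cosine"`.
#' @param vote_grid Candidate vote rules `"majority"`,
#'   `"similarity_weighted"`.
#' @return An `intention_model` (type `"knn"`) storing the scaled
#'   training set and the selected configuration (`$k`, `$metric`,
#'   `$vote`, `$cv_loss`).
#' @export
train_knn <- function(X, y, k_grid = seq(1, 25, by = 2),
                      metric_grid = knn_metrics,
                      vote_grid = c("majority", "similarity_weighted")) {
  Xm <- if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(Xm) == length(y), length(k_grid) > 0, length(metric_grid) > 0)
  if (!all(y %in% c(-1, 0, 1))) stop("labels must be in {-1, 0, +1}")
  n <- nrow(Xm)
  if (n < 25) stop("fewer than 5 training rows per fold")
  sc <- scaler_fit(Xm)
  Xs <- scaler_apply(sc, Xm)
  fold <- cut(seq_len(n), 5, labels = FALSE)
  vote_short <- function(v) if (v == "majority") "majority" else "similarity"
  best <- NULL
  for (metric in metric_grid) {
    # per fold: distance from validation rows to the other folds' rows
    fold_err <- array(NA_real_, c(5, length(k_grid), length(vote_grid)))
    for (f in 1:5) {
      va <- which(fold == f); tr <- which(fold != f)
      D <- knn_distance(Xs[va, , drop = FALSE], Xs[tr, , drop = FALSE], metric)
      for (ki in seq_along(k_grid)) {
        k <- min(k_grid[ki], length(tr))
        for (vi in seq_along(vote_grid)) {
          pred <- knn_vote(D, y[tr], k, vote_short(vote_grid[vi]))
          fold_err[f, ki, vi] <- mean(pred != y[va])
        }
      }
    }
    for (ki in seq_along(k_grid)) for (vi in seq_along(vote_grid)) {
      loss <- mean(fold_err[, ki, vi])
      if (is.null(best) || loss < best$cv_loss - 1e-12)
        best <- list(k = k_grid[ki], metric = metric,
                     vote = vote_grid[vi], cv_loss = loss)
    }
  }
  structure(list(type = "knn", train_X = Xs, train_y = y, scaler = sc,
                 n_inputs = ncol(Xm), k = best$k, metric = best$metric,
                 vote = best$vote, cv_loss = best$cv_loss,
                 train_n = n),
            class = "intention_model")
}

#' Predict class codes with a fitted k-nn model
#'
#' @param m An `intention_model` of type `"knn"`.
#' @param X Query feature matrix (or `feature_matrix`).
#' @return Class series in `{-1, 0, +1}`. Vote ties go to rest when rest
#'   is among the tied classes, else to the smallest class code.
#' @export
predict_knn <- function(m, X) {
  stopifnot(inherits(m, "intention_model"), m$type == "knn")
  Xm <- if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
  if (ncol(Xm) != m$n_inputs)
    stop("dimension mismatch: model expects ", m$n_inputs, " inputs")
  D <- knn_distance(scaler_apply(m$scaler, Xm), m$train_X, m$metric)
  k <- min(m$k, nrow(m$train_X))
  vote <- if (m$vote == "majority") "majority" else "similarity"
  as.numeric(knn_vote(D, m$train_y, k, vote))
}

#' @export
print.intention_model <- function(x, ...) {
  if (x$type == "mlp")
    cat("<intention_model> MLP ", x$n_inputs, "-", x$n_hidden,
        "-1, trained on ", x$train_n, " rows\n", sep = "")
  else
    cat("<intention_model> k-nn, k=", x$k, ", ", x$metric, ", ", x$vote,
        " vote (CV loss ", signif(x$cv_loss, 3), ")\n", sep = "")
  invisible(x)
}

#' Residual-limb motion detector
#'
#' Flags samples where the shoulder is moving: the shoulder angle is
#' median-filtered (5 samples) to kill single-sample glitches, the
#' angular speed taken by finite differences, and a sample is flagged
#' when the speed exceeds `vel_thresh_deg_s` sustained for at least
#' `hold_ms` -- brief crossings are suppressed.
#'
#' @param kin A [kinematics_trace()].
#' @param vel_thresh_deg_s Speed threshold in degrees/second (default 10).
#' @param hold_ms Minimum duration a crossing must last (default 200).
#' @return Logical series, `TRUE` where the limb is judged to be moving.
#' @export
limb_motion_flag <- function(kin, vel_thresh_deg_s = 10, hold_ms = 200) {
  stopifnot(inherits(kin, "kinematics_trace"))
  x <- stats::runmed(kin$shoulder_deg, 5, endrule = "median")
  n <- length(x)
  v <- c(diff(x), 0) * kin$fs          # speed over the upcoming interval
  flag <- abs(v) > vel_thresh_deg_s
  hold <- max(1L, as.integer(round(hold_ms * kin$fs / 1000)))
  r <- rle(flag)
  r$values[r$values & r$lengths < hold] <- FALSE
  inverse.rle(r)
}

#' Gate classifier output against residual-limb motion
#'
#' The final prediction is rest unless the residual limb is actually
#' moving; when it is, the classifier's class passes through. This
#' prevents false triggers while the user is at rest, since shoulder
#' motion alone cannot distinguish lifting from reaching but its absence
#' rules both out.
#'
#' | classifier output | limb moving | final |
#' |---|---|---|
#' | rest | no | rest |
#' | reaching | no | rest |
#' | lifting | no | rest |
#' | rest | yes | rest |
#' | reaching | yes | reaching |
#' | lifting | yes | lifting |
#'
#' @param pred Class series in `{-1, 0, +1}`.
#' @param moving Logical series, same length.
#' @return Gated class series.
#' @export
gate <- function(pred, moving) {
  if (length(pred) != length(moving)) stop("length mismatch")
  ifelse(moving, pred, 0)
}
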