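#' Per-sample classification accuracy
#'
#' @param pred,truth Class series in `{-1, 0, +1}`, equal length.
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  stopifnot(all(pred %in% c(-1, 0, 1)), all(truth %in% c(-1, 0, 1)))
  100 * mean(pred == truth)
}

#' Confusion counts over the three classes
#'
#' @param pred,truth Class series in `{-1, 0, +1}`.
#' @return 3x3 integer matrix, rows = truth, columns = prediction,
#'   ordered reaching / rest / lifting.
#' @export
confusion_counts <- function(pred, truth) {
  lv <- c(-1, 0, 1)
  tab <- table(factor(truth, lv), factor(pred, lv))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(truth = c("reaching", "rest", "lifting"),
                              pred = c("reaching", "rest", "lifting")))
  m
}

#' Empirical chance level
#'
#' `prior_max` is the accuracy of always predicting the most frequent
#' class (100 x the maximum class proportion). `permutation` re-scores a
#' given prediction series against label-shuffled copies of the truth and
#' averages, estimating the accuracy obtainable with no real
#' stimulus-response association.
#'
#' @param truth Class series in `{-1, 0, +1}`.
#' @param method `"prior_max"` (default) or `"permutation"`.
#' @param pred Prediction series (required for `"permutation"`).
#' @param n_perm Number of shuffles (default 200).
#' @param seed RNG seed for the shuffles.
#' @return Chance level in percent.
#' @export
chance_level <- function(truth, method = c("prior_max", "permutation"),
                         pred = NULL, n_perm = 200, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(truth) > 0)
  if (method == "prior_max")
    return(100 * max(tabulate(factor(truth, c(-1, 0, 1)), 3)) / length(truth))
  if (is.null(pred)) stop("permutation chance needs the prediction series")
  with_seed(seed, {
    mean(vapply(seq_len(n_perm), function(i)
      classification_accuracy(pred, sample(truth)), 0))
  })
}

#' One-sided exact binomial significance of an accuracy
#'
#' Probability of observing at least the achieved number of correct
#' samples if each sample were an independent success with probability
#' `chance/100`.
#'
#' @param accuracy Observed accuracy in percent.
#' @param chance Chance level in percent, `0 <= chance < 100`.
#' @param n Number of test samples.
#' @return One-sided p-value.
#' @export
binomial_significance <- function(accuracy, chance, n) {
  stopifnot(n >= 1, chance >= 0, chance < 100)
  k <- round(accuracy * n / 100)
  stats::pbinom(k - 1, n, chance / 100, lower.tail = FALSE)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Aggregate per-subject accuracies
#'
#' Mean and population standard deviation (divide by N), both rounded
#' half-up to one decimal -- the convention used in study summary tables
#' and error bars.
#'
#' @param per_subject Numeric vector of per-subject accuracies (percent).
#' @return Named vector `c(mean, sd)`.
#' @export
aggregate_accuracy_table <- function(per_subject) {
  stopifnot(length(per_subject) >= 1)
  m <- mean(per_subject)
  s <- sqrt(mean((per_subject - m)^2))
  c(mean = round_half_up(m), sd = round_half_up(s))
}

feature_default_channels <- function(feature) {
  if (feature == "alpha_power") c("P3", "Pz") else c("FC2", "C2")
}

feature_series_for <- function(car, feature, channels) {
  switch(feature,
         mrcp = mrcp_amplitude(car, channels = channels),
         delta_power = band_power(car, "delta", channels = channels),
         alpha_power = band_power(car, "alpha", channels = channels),
         rms = rms_series(car, channels = channels),
         stop("unknown feature kind: ", feature))
}

#' Extract classifier-ready features from a session
#'
#' Runs CAR, the requested feature family (or all four for
#' `"combined"`) on its conventional channels, and the time-delay
#' embedding; aligns labels and the limb-motion flag to the resulting
#' rows and optionally thins them.
#'
#' @param session A [session_bundle()].
#' @param feature One of `"mrcp"`, `"delta_power"`, `"alpha_power"`,
#'   `"rms"`, `"combined"`.
#' @param channels Optional channel override (ignored for combined).
#' @param lag_ms,n_lags Delay-embedding settings, see
#'   [build_feature_matrix()].
#' @param stride Keep every `stride`-th row (default 25, i.e. 20
#'   classifier decisions per second at a 500 Hz EEG).
#' @return List with `fm` (the `feature_matrix`), `y` (labels per row)
#'   and `moving` (limb flag per row).
#' @export
featurize_session <- function(session, feature = "mrcp", channels = NULL,
                              lag_ms = 250, n_lags = 3, stride = 25L) {
  stopifnot(inherits(session, "session_bundle"))
  car <- common_average_reference(session$eeg)
  kinds <- if (feature == "combined")
    c("mrcp", "delta_power", "alpha_power", "rms") else feature
  series <- list()
  for (kd in kinds) {
    ch <- if (feature == "combined" || is.null(channels))
      feature_default_channels(kd) else channels
    series <- c(series, unname(feature_series_for(car, kd, ch)))
  }
  fm <- build_feature_matrix(series, lag_ms = lag_ms, n_lags = n_lags)
  fm <- decimate_feature_matrix(fm, stride)
  y <- session$labels[fm$row_index]
  moving <- limb_motion_flag(session$kin)[fm$row_index]
  list(fm = fm, y = y, moving = moving)
}

#' Decode one session end to end and evaluate
#'
#' Chronological 80/20 split of the feature rows, classifier training on
#' the first 80%, gated evaluation on the held-out 20%: prediction, limb
#' gating, per-sample accuracy, prior-max chance level and exact binomial
#' significance.
#'
#' @param session A [session_bundle()].
#' @param feature Feature family, see [featurize_session()].
#' @param classifier `"mlp"` or `"knn"`.
#' @param train_fraction Chronological training fraction (default 0.8).
#' @param gate_output Apply the residual-limb gate (default TRUE).
#' @param stride Feature-row thinning, see [featurize_session()].
#' @param seed Seed for classifier initialisation.
#' @param ... Passed to [train_mlp()] or [train_knn()].
#' @return An `evaluation_report`.
#' @export
evaluate_session <- function(session, feature = "mrcp",
                             classifier = c("mlp", "knn"),
                             train_fraction = 0.8, gate_output = TRUE,
                             stride = 25L, seed = 1, ...) {
  classifier <- match.arg(classifier)
  fz <- featurize_session(session, feature, stride = stride)
  n <- nrow(fz$fm$X)
  n_train <- floor(train_fraction * n)
  tr <- seq_len(n_train)
  te <- (n_train + 1L):n
  Xtr <- fz$fm$X[tr, , drop = FALSE]
  Xte <- fz$fm$X[te, , drop = FALSE]
  if (classifier == "mlp") {
    n_hidden <- if (feature == "combined") 80L else 30L
    model <- train_mlp(Xtr, fz$y[tr], n_hidden = n_hidden, seed = seed, ...)
    pred <- discretize(predict_continuous(model, Xte))
  } else {
    model <- train_knn(Xtr, fz$y[tr], ...)
    pred <- predict_knn(model, Xte)
  }
  final <- if (gate_output) gate(pred, fz$moving[te]) else pred
  truth <- fz$y[te]
  acc <- classification_accuracy(final, truth)
  ch <- chance_level(truth, "prior_max")
  structure(list(subject = session$subject_id, feature = feature,
                 classifier = classifier,
                 accuracy = acc, chance = ch,
                 p_value = binomial_significance(acc, ch, length(truth)),
                 confusion = confusion_counts(final, truth),
                 n_test = length(truth), n_train = n_train,
                 model = model),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$subject, " / ", x$feature, " / ",
      x$classifier, ": accuracy ", round_half_up(x$accuracy),
      "% (chance ", round_half_up(x$chance), "%, p = ",
      signif(x$p_value, 3), ", n = ", x$n_test, ")\n", sep = "")
  invisible(x)
}

#' Serialise / restore an evaluation report
#'
#' Text round-trip of the report's numbers (the fitted model itself is
#' not serialised).
#'
#' @param report An `evaluation_report`.
#' @param path YAML file path.
#' @return `path` / the restored `evaluation_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  out <- report[c("subject", "feature", "classifier", "accuracy",
                  "chance", "p_value", "n_test", "n_train")]
  out$confusion <- as.list(as.data.frame(report$confusion))
  writeLines(yaml::as.yaml(out), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  r <- yaml::read_yaml(path)
  conf <- matrix(unlist(r$confusion), 3, 3,
                 dimnames = list(truth = c("reaching", "rest", "lifting"),
                                 pred = c("reaching", "rest", "lifting")))
  structure(list(subject = r$subject, feature = r$feature,
                 classifier = r$classifier, accuracy = r$accuracy,
                 chance = r$chance, p_value = r$p_value,
                 confusion = conf, n_test = r$n_test, n_train = r$n_train,
                 model = NULL),
            class = "evaluation_report")
}

#' Run the full decoding pipeline over a study
#'
#' For each session and requested feature/classifier combination:
#' CAR, feature extraction on the conventional channels, delay embedding,
#' chronological 80/20 split, classifier training, residual-limb gating
#' and evaluation. Deterministic for fixed seeds.
#'
#' @param sessions List of [session_bundle()]s (or a single one), or a
#'   character vector of session directories for [read_session()].
#' @param features Feature families to run (default `"mrcp"`).
#' @param classifiers Classifier kinds to run (default `"mlp"`).
#' @param stride,train_fraction,gate_output,seed See [evaluate_session()].
#' @param verbose Log per-stage progress to stderr.
#' @param ... Passed through to the trainers.
#' @return A `pipeline_result`: list of `evaluation_report`s plus a
#'   summary data frame (`$summary`) with one row per report and the
#'   aggregate mean and SD per feature/classifier.
#' @export
run_pipeline <- function(sessions, features = "mrcp", classifiers = "mlp",
                         stride = 25L, train_fraction = 0.8,
                         gate_output = TRUE, seed = 1, verbose = FALSE,
                         ...) {
  if (is.character(sessions)) sessions <- lapply(sessions, read_session)
  if (inherits(sessions, "session_bundle")) sessions <- list(sessions)
  reports <- list()
  for (cl in classifiers) for (ft in features) for (s in sessions) {
    if (verbose)
      message(sprintf("[%s] %s / %s / %s", format(Sys.time(), "%H:%M:%S"),
                      s$subject_id, ft, cl))
    reports[[length(reports) + 1L]] <-
      evaluate_session(s, feature = ft, classifier = cl,
                       train_fraction = train_fraction,
                       gate_output = gate_output, stride = stride,
                       seed = seed, ...)
  }
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(subject = r$subject, feature = r$feature,
               classifier = r$classifier, accuracy = r$accuracy,
               chance = r$chance, p_value = r$p_value, n_test = r$n_test)))
  agg <- do.call(rbind, lapply(
    split(summary, list(summary$feature, summary$classifier), drop = TRUE),
    function(g) {
      a <- aggregate_accuracy_table(g$accuracy)
      data.frame(feature = g$feature[1], classifier = g$classifier[1],
                 mean = a["mean"], sd = a["sd"], row.names = NULL)
    }))
  structure(list(reports = reports, summary = summary, aggregate = agg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$reports), " report(s)\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat("aggregate (mean +/- population SD):\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
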