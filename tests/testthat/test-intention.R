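test_that("the MLP learns a separable three-class problem", {
  fx <- separable_clusters()
  m <- train_mlp(fx$X, fx$y, n_hidden = 30, epochs = 500, seed = 1)
  acc <- classification_accuracy(discretize(predict_continuous(m, fx$X)),
                                 fx$y)
  expect_gte(acc, 95)
  expect_lte(m$fit$epochs_run, 500)
  # mean absolute deviation from the class targets is small
  expect_lte(mean(abs(predict_continuous(m, fx$X) - fx$y)), 0.2)
})

test_that("MLP training is deterministic and its loss non-increasing", {
  fx <- separable_clusters(n_per = 60)
  m1 <- train_mlp(fx$X, fx$y, epochs = 300, seed = 9)
  m2 <- train_mlp(fx$X, fx$y, epochs = 300, seed = 9)
  expect_identical(m1$fit$W1, m2$fit$W1)
  expect_identical(m1$fit$W2, m2$fit$W2)

  tr <- m1$fit$loss_trace
  expect_true(all(diff(tr) <= 0.01 * tr[-length(tr)]))

  m3 <- train_mlp(fx$X, fx$y, epochs = 300, seed = 10)
  expect_false(identical(m1$fit$W1, m3$fit$W1))
})

test_that("MLP guards its contracts", {
  fx <- separable_clusters(n_per = 40)
  expect_error(train_mlp(fx$X, rep(0, nrow(fx$X))), "degenerate labels")
  expect_error(train_mlp(fx$X, rep(2, nrow(fx$X))), "labels")
  m <- train_mlp(fx$X, fx$y, epochs = 100, seed = 1)
  expect_error(predict_continuous(m, fx$X[, 1, drop = FALSE]),
               "dimension mismatch")
  # bounded output everywhere, even far outside the training cloud
  wild <- matrix(runif(200, -100, 100), 100, 2)
  out <- predict_continuous(m, wild)
  expect_true(all(out >= -1 & out <= 1))
})

test_that("uninformative features yield no class separation", {
  set.seed(21)
  n <- 600
  X <- matrix(rnorm(n * 4), n, 4)
  y <- sample(c(-1, 0, 1), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  m <- train_mlp(X, y, epochs = 200, seed = 1)
  out <- predict_continuous(m, X)
  # class-conditional output means are statistically indistinguishable
  for (cl in c(-1, 1)) {
    a <- out[y == cl]; b <- out[y == 0]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), max(2 * se, 0.05))
  }
})

test_that("discretize maps continuous output with ties to rest", {
  expect_equal(discretize(c(0, 0.9, -0.9, 0.5, -0.5, 0.51, -0.51)),
               c(0, 1, -1, 0, 0, 1, -1))
})

test_that("cross-validated k-nn solves well-separated clusters", {
  fx <- separable_clusters(n_per = 60, seed = 5)
  set.seed(6)
  shuf <- sample(nrow(fx$X))
  tr <- shuf[1:120]; te <- shuf[121:180]
  m <- train_knn(fx$X[tr, ], fx$y[tr])
  expect_gte(classification_accuracy(predict_knn(m, fx$X[te, ]), fx$y[te]),
             95)
  expect_true(m$k %in% seq(1, 25, 2))
  expect_true(m$metric %in% c("euclidean", "cityblock", "cosine"))
})

test_that("1-nn recalls its own training points", {
  fx <- separable_clusters(n_per = 20, seed = 8)
  m <- train_knn(fx$X, fx$y, k_grid = 1, metric_grid = "euclidean",
                 vote_grid = "majority")
  expect_equal(classification_accuracy(predict_knn(m, fx$X), fx$y), 100)
})

test_that("k-nn predictions match a brute-force oracle", {
  set.seed(13)
  Xtr <- matrix(rnorm(200 * 3), 200, 3)
  ytr <- sample(c(-1, 0, 1), 200, replace = TRUE)
  Xq <- matrix(rnorm(50 * 3), 50, 3)
  for (metric in c("euclidean", "cityblock")) {
    for (vote in c("majority", "similarity_weighted")) {
      m <- train_knn(Xtr, ytr, k_grid = 5, metric_grid = metric,
                     vote_grid = vote)
      pred <- predict_knn(m, Xq)
      # independent oracle: explicit per-query loop on scaled data
      mu <- colMeans(Xtr); sd_ <- apply(Xtr, 2, sd)
      A <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
      B <- sweep(sweep(Xq, 2, mu), 2, sd_, "/")
      oracle <- vapply(seq_len(nrow(B)), function(i) {
        d <- if (metric == "euclidean") sqrt(colSums((t(A) - B[i, ])^2))
             else colSums(abs(t(A) - B[i, ]))
        nn <- order(d)[1:5]
        w <- if (vote == "majority") rep(1, 5) else 1 / (1 + d[nn])
        sums <- tapply(w, factor(ytr[nn], c(-1, 0, 1)), sum)
        sums[is.na(sums)] <- 0
        cand <- as.numeric(names(sums)[sums == max(sums)])
        if (0 %in% cand) 0 else min(cand)
      }, 0)
      expect_equal(pred, oracle, label = paste(metric, vote))
    }
  }
})

test_that("majority and similarity votes agree under absolute majority", {
  # one class holds > k/2 of the neighbourhood: both rules must pick it
  set.seed(17)
  for (rep in 1:20) {
    Xtr <- matrix(rnorm(30 * 2), 30, 2)
    ytr <- c(rep(1, 18), rep(-1, 6), rep(0, 6))
    q <- matrix(rnorm(2, 0, 0.3), 1, 2)
    m_maj <- train_knn(Xtr, ytr, k_grid = 3, metric_grid = "euclidean",
                       vote_grid = "majority")
    m_sim <- train_knn(Xtr, ytr, k_grid = 3, metric_grid = "euclidean",
                       vote_grid = "similarity_weighted")
    d <- sqrt(colSums((t(m_sim$train_X) - as.numeric(
      sweep(sweep(q, 2, m_sim$scaler$mean), 2, m_sim$scaler$sd, "/")))^2))
    top <- ytr[order(d)[1:3]]
    counts <- table(factor(top, c(-1, 0, 1)))
    if (max(counts) > 3 / 2) {
      expect_equal(predict_knn(m_maj, q), predict_knn(m_sim, q))
    }
  }
})

test_that("k-nn tie-breaks favour rest, then the smaller code", {
  # two training points, equidistant query
  Xtr <- rbind(c(0, 0), c(2, 0))
  expand <- function(y) {   # duplicate to satisfy the 25-row minimum
    list(X = Xtr[rep(1:2, 15), ], y = rep(y, 15))
  }
  f <- expand(c(0, 1))
  m <- train_knn(f$X, f$y, k_grid = 2, metric_grid = "euclidean",
                 vote_grid = "majority")
  expect_equal(predict_knn(m, matrix(c(1, 0), 1)), 0)

  f2 <- expand(c(-1, 1))
  m2 <- train_knn(f2$X, f2$y, k_grid = 2, metric_grid = "euclidean",
                  vote_grid = "majority")
  expect_equal(predict_knn(m2, matrix(c(1, 0), 1)), -1)

  expect_error(train_knn(Xtr, c(0, 1)), "fewer than 5")
})

test_that("the limb-motion detector flags sustained velocity only", {
  fs <- 500
  still <- kinematics_trace(fs, rep(20, 3000), rep(175, 3000),
                            matrix(0, 3000, 2))
  expect_false(any(limb_motion_flag(still)))

  kin <- ramp_kin()
  flag <- limb_motion_flag(kin)
  expect_true(all(flag[5300:6100]))     # inside the 45 deg/s ramp
  expect_false(any(flag[1:5000]))
  expect_false(any(flag[6500:7000]))

  spiky <- rep(10, 3000)
  spiky[1500] <- 11
  kin_sp <- kinematics_trace(fs, spiky, rep(175, 3000), matrix(0, 3000, 2))
  expect_false(any(limb_motion_flag(kin_sp)))
})

test_that("the residual-limb gate implements the full rule table", {
  preds <- c(-1, 0, 1, -1, 0, 1)
  moving <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(gate(preds, moving), c(0, 0, 0, -1, 0, 1))
  expect_error(gate(c(1, 0), TRUE), "length mismatch")
})
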