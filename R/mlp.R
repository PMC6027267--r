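# Single-hidden-layer perceptron trained by full-batch error
# backpropagation on mean squared error.
#
# The step size adapts deterministically: a step that would increase the
# loss is retried with half the step until it decreases (or the step
# underflows), an accepted step grows it by 5%. This keeps the recorded
# loss trace non-increasing and the whole trajectory an exact function of
# (data, seed), which the classifier contracts rely on.

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(d, h, o, seed) {
  with_seed(seed, {
    r1 <- 1 / sqrt(d + 1)
    r2 <- 1 / sqrt(h + 1)
    list(W1 = matrix(stats::runif((d + 1) * h, -r1, r1), d + 1, h),
         W2 = matrix(stats::runif((h + 1) * o, -r2, r2), h + 1, o))
  })
}

mlp_forward <- function(w, X, out_act) {
  H <- sigmoid(cbind(1, X) %*% w$W1)
  Z <- cbind(1, H) %*% w$W2
  Yhat <- if (out_act == "tanh_unit") 2 * sigmoid(Z) - 1 else Z
  list(H = H, Yhat = Yhat)
}

mlp_loss <- function(w, X, Y, out_act) {
  mean((mlp_forward(w, X, out_act)$Yhat - Y)^2)
}

mlp_grad <- function(w, X, Y, out_act) {
  fw <- mlp_forward(w, X, out_act)
  n <- nrow(X)
  dY <- 2 * (fw$Yhat - Y) / (n * ncol(Y))
  dZ <- if (out_act == "tanh_unit") dY * (1 - fw$Yhat^2) / 2 else dY
  dW2 <- crossprod(cbind(1, fw$H), dZ)
  dH <- dZ %*% t(w$W2[-1, , drop = FALSE])
  dA <- dH * fw$H * (1 - fw$H)
  dW1 <- crossprod(cbind(1, X), dA)
  list(W1 = dW1, W2 = dW2)
}

# out_act: "tanh_unit" (bounded (-1,1) classifier output) or "linear";
# optimizer: "gd" (adaptive-step full-batch gradient descent) or "rprop"
# (iRprop+ per-weight sign steps; converges much faster on the stiff
# regression surfaces of the kinematic estimators)
mlp_fit <- function(X, Y, n_hidden, out_act = "tanh_unit",
                    lr = 0.01, epochs = 2000, tol = 1e-6, seed = 1,
                    optimizer = c("gd", "rprop")) {
  optimizer <- match.arg(optimizer)
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 2)
  if (optimizer == "rprop")
    return(mlp_fit_rprop(X, Y, n_hidden, out_act, lr, epochs, tol, seed))
  w <- mlp_init(ncol(X), n_hidden, ncol(Y), seed)
  loss <- mlp_loss(w, X, Y, out_act)
  trace <- numeric(epochs)
  used <- 0L
  patience <- 0L
  for (e in seq_len(epochs)) {
    g <- mlp_grad(w, X, Y, out_act)
    repeat {
      cand <- list(W1 = w$W1 - lr * g$W1, W2 = w$W2 - lr * g$W2)
      cl <- mlp_loss(cand, X, Y, out_act)
      if (cl <= loss || lr < 1e-12) break
      lr <- lr / 2
    }
    if (cl > loss) break           # step underflow: converged
    improvement <- loss - cl
    w <- cand; loss <- cl
    used <- e; trace[e] <- cl
    # stop once progress has stalled for a stretch, not on one slow epoch
    patience <- if (improvement < tol) patience + 1L else 0L
    if (patience >= 10L) break
    lr <- lr * 1.1
  }
  structure(list(W1 = w$W1, W2 = w$W2, out_act = out_act,
                 n_hidden = n_hidden, loss = loss,
                 loss_trace = trace[seq_len(used)], epochs_run = used,
                 seed = seed),
            class = "mlp_fit")
}

# iRprop+: per-weight step sizes grown 1.2x while the gradient keeps its
# sign, shrunk 0.5x (with the step undone if the loss rose) on a sign
# flip. Full-batch and an exact function of (data, seed).
mlp_fit_rprop <- function(X, Y, n_hidden, out_act, lr, epochs, tol, seed) {
  w <- mlp_init(ncol(X), n_hidden, ncol(Y), seed)
  d <- lapply(w, function(m) array(lr, dim(m)))
  gp <- lapply(w, function(m) m * 0)
  dw_prev <- lapply(w, function(m) m * 0)
  prev_loss <- Inf
  trace <- numeric(epochs)
  used <- 0L
  patience <- 0L
  for (e in seq_len(epochs)) {
    g <- mlp_grad(w, X, Y, out_act)
    loss <- mlp_loss(w, X, Y, out_act)
    for (nm in names(w)) {
      s <- sign(g[[nm]]) * sign(gp[[nm]])
      d[[nm]][s > 0] <- pmin(d[[nm]][s > 0] * 1.2, 1)
      d[[nm]][s < 0] <- pmax(d[[nm]][s < 0] * 0.5, 1e-9)
      step <- -sign(g[[nm]]) * d[[nm]]
      if (loss > prev_loss) step[s < 0] <- -dw_prev[[nm]][s < 0]
      g[[nm]][s < 0] <- 0
      w[[nm]] <- w[[nm]] + step
      dw_prev[[nm]] <- step
      gp[[nm]] <- g[[nm]]
    }
    used <- e; trace[e] <- loss
    patience <- if (prev_loss - loss < tol) patience + 1L else 0L
    if (patience >= 25L) break
    prev_loss <- loss
  }
  loss <- mlp_loss(w, X, Y, out_act)
  structure(list(W1 = w$W1, W2 = w$W2, out_act = out_act,
                 n_hidden = n_hidden, loss = loss,
                 loss_trace = trace[seq_len(used)], epochs_run = used,
                 seed = seed),
            class = "mlp_fit")
}

mlp_predict <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(fit$W1) - 1L)
    stop("dimension mismatch: model expects ", nrow(fit$W1) - 1L,
         " inputs, got ", ncol(X))
  mlp_forward(fit, X, fit$out_act)$Yhat
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat("<mlp_fit> ", nrow(x$W1) - 1, "-", x$n_hidden, "-", ncol(x$W2),
      " (", x$out_act, "), final MSE ", signif(x$loss, 4),
      " after ", x$epochs_run, " epochs\n", sep = "")
  invisible(x)
}

# column z-scoring with stored statistics (training partition only)
scaler_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

scaler_apply <- function(sc, X) {
  sweep(sweep(as.matrix(X), 2, sc$mean), 2, sc$sd, "/")
}
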