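# Two-hidden-layer feed-forward regressor: per-layer inverted dropout,
# activation in {tanh, swish, linear, relu}, ADAM optimizer, MAE loss.
# Written against base matrix algebra; sized for tabular EHR problems
# (thousands of rows, tens of columns), where this is fast enough that a
# heavyweight deep-learning backend would buy nothing.

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    linear = list(f = identity, df = function(z, a) rep(1, length(z))),
    swish = list(
      f = function(z) z * stats::plogis(z),
      df = function(z, a) {
        s <- stats::plogis(z)
        a + s * (1 - a)
      }),
    abort(sprintf("unknown activation '%s'", name), "loscade_spec_error"))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# hp: hidden1, hidden2, activation1, activation2, dropout1, dropout2,
#     learning_rate, epochs, batch_size
ann_fit <- function(X, y, hp) {
  p <- ncol(X); n <- nrow(X)
  h1 <- as.integer(hp$hidden1); h2 <- as.integer(hp$hidden2)
  a1 <- act_fun(hp$activation1); a2 <- act_fun(hp$activation2)
  par <- list(W1 = glorot(p, h1), b1 = rep(0, h1),
              W2 = glorot(h1, h2), b2 = rep(0, h2),
              W3 = glorot(h2, 1L), b3 = 0)
  m <- lapply(par, function(w) w * 0)
  v <- lapply(par, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  bs <- max(1L, as.integer(hp$batch_size))
  for (epoch in seq_len(hp$epochs)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      b <- idx[start:min(start + bs - 1L, n)]
      nb <- length(b)
      Xb <- X[b, , drop = FALSE]
      yb <- y[b]

      Z1 <- sweep(Xb %*% par$W1, 2, par$b1, "+")
      A1 <- a1$f(Z1)
      M1 <- (matrix(runif(nb * h1), nb, h1) >= hp$dropout1) /
        (1 - hp$dropout1)
      A1d <- A1 * M1
      Z2 <- sweep(A1d %*% par$W2, 2, par$b2, "+")
      A2 <- a2$f(Z2)
      M2 <- (matrix(runif(nb * h2), nb, h2) >= hp$dropout2) /
        (1 - hp$dropout2)
      A2d <- A2 * M2
      out <- drop(A2d %*% par$W3) + par$b3

      d_out <- sign(out - yb) / nb            # MAE gradient
      gW3 <- crossprod(A2d, d_out)
      gb3 <- sum(d_out)
      dA2 <- (d_out %*% t(par$W3)) * M2
      dZ2 <- dA2 * matrix(a2$df(Z2, A2), nb, h2)
      gW2 <- crossprod(A1d, dZ2)
      gb2 <- colSums(dZ2)
      dA1 <- (dZ2 %*% t(par$W2)) * M1
      dZ1 <- dA1 * matrix(a1$df(Z1, A1), nb, h1)
      gW1 <- crossprod(Xb, dZ1)
      gb1 <- colSums(dZ1)

      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3)
      t_step <- t_step + 1L
      for (k in names(par)) {
        m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grads[[k]]
        v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grads[[k]]^2
        mhat <- m[[k]] / (1 - beta1^t_step)
        vhat <- v[[k]] / (1 - beta2^t_step)
        par[[k]] <- par[[k]] - hp$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(par = par, act = c(hp$activation1, hp$activation2))
}

ann_predict <- function(fit, X) {
  a1 <- act_fun(fit$act[1]); a2 <- act_fun(fit$act[2])
  par <- fit$par
  A1 <- a1$f(sweep(X %*% par$W1, 2, par$b1, "+"))
  A2 <- a2$f(sweep(A1 %*% par$W2, 2, par$b2, "+"))
  drop(A2 %*% par$W3) + par$b3
}
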