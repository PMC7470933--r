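# Native neural-network decoders: a two-hidden-layer feedforward net and
# simple RNN / GRU / LSTM cells unrolled over the B-bin lag window, all
# trained with Adam on mean-squared error. Gradients are exact analytic
# backpropagation (verified against finite differences in the test suite).
# All randomness (initialisation, shuffling, dropout) draws from R's RNG,
# so fits are reproducible given a seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -r, r), nin, nout)
}

adam_step <- function(params, grads, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^t)
    vhat <- st$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, st = st)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0))

## ---- feedforward (two equal hidden layers, ReLU, dropout) ----

mlp_init <- function(P, H, d)
  list(W1 = glorot(P, H), b1 = matrix(0, 1, H),
       W2 = glorot(H, H), b2 = matrix(0, 1, H),
       W3 = glorot(H, d), b3 = matrix(0, 1, d))

mlp_forward <- function(p, X, dropout = 0, train = FALSE) {
  A1 <- X %*% p$W1; A1 <- sweep(A1, 2, p$b1, "+"); H1 <- pmax(A1, 0)
  M1 <- NULL
  if (train && dropout > 0) {
    M1 <- matrix(rbinom(length(H1), 1, 1 - dropout), nrow(H1)) / (1 - dropout)
    H1 <- H1 * M1
  }
  A2 <- H1 %*% p$W2; A2 <- sweep(A2, 2, p$b2, "+"); H2 <- pmax(A2, 0)
  M2 <- NULL
  if (train && dropout > 0) {
    M2 <- matrix(rbinom(length(H2), 1, 1 - dropout), nrow(H2)) / (1 - dropout)
    H2 <- H2 * M2
  }
  Yh <- H2 %*% p$W3; Yh <- sweep(Yh, 2, p$b3, "+")
  list(Yh = Yh, X = X, A1 = A1, H1 = H1, A2 = A2, H2 = H2, M1 = M1, M2 = M2)
}

mlp_backward <- function(p, cache, dY) {
  dW3 <- crossprod(cache$H2, dY); db3 <- colSums(dY)
  dH2 <- dY %*% t(p$W3)
  if (!is.null(cache$M2)) dH2 <- dH2 * cache$M2
  dA2 <- dH2 * (cache$A2 > 0)
  dW2 <- crossprod(cache$H1, dA2); db2 <- colSums(dA2)
  dH1 <- dA2 %*% t(p$W2)
  if (!is.null(cache$M1)) dH1 <- dH1 * cache$M1
  dA1 <- dH1 * (cache$A1 > 0)
  dW1 <- crossprod(cache$X, dA1); db1 <- colSums(dA1)
  list(W1 = dW1, b1 = matrix(db1, 1), W2 = dW2, b2 = matrix(db2, 1),
       W3 = dW3, b3 = matrix(db3, 1))
}

## ---- recurrent cells (unrolled over B steps, readout from final state) ----

rnn_init <- function(N, H, d)
  list(Wx = glorot(N, H), Wh = glorot(H, H), b = matrix(0, 1, H),
       Wo = glorot(H, d), bo = matrix(0, 1, d))

rnn_forward <- function(p, X3, dropout = 0, train = FALSE) {
  K <- dim(X3)[1]; B <- dim(X3)[3]; H <- ncol(p$Wh)
  X3 <- seq_input_dropout(X3, dropout, train)
  hs <- vector("list", B + 1)
  hs[[1]] <- matrix(0, K, H)
  for (j in seq_len(B)) {
    a <- X3[, , j, drop = FALSE]
    dim(a) <- dim(X3)[1:2]
    z <- a %*% p$Wx + hs[[j]] %*% p$Wh
    hs[[j + 1]] <- tanh(sweep(z, 2, p$b, "+"))
  }
  hB <- hs[[B + 1]]
  Yh <- sweep(hB %*% p$Wo, 2, p$bo, "+")
  list(Yh = Yh, hs = hs, hB = hB, M = NULL, X3 = X3, B = B)
}

# inverted dropout on the input features, one mask per sample shared
# across all B time steps (the masked tensor feeds the backward pass)
seq_input_dropout <- function(X3, dropout, train) {
  if (!train || dropout <= 0) return(X3)
  Mx <- matrix(rbinom(dim(X3)[1] * dim(X3)[2], 1, 1 - dropout),
               dim(X3)[1]) / (1 - dropout)
  X3 * array(Mx, dim(X3))
}

rnn_backward <- function(p, cache, dY) {
  B <- cache$B
  dWo <- crossprod(cache$hB, dY); dbo <- colSums(dY)
  dh <- dY %*% t(p$Wo)
  if (!is.null(cache$M)) dh <- dh * cache$M
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- numeric(ncol(p$Wh))
  for (j in B:1) {
    h <- cache$hs[[j + 1]]
    delta <- dh * (1 - h^2)
    x <- cache$X3[, , j, drop = FALSE]; dim(x) <- dim(cache$X3)[1:2]
    dWx <- dWx + crossprod(x, delta)
    dWh <- dWh + crossprod(cache$hs[[j]], delta)
    db <- db + colSums(delta)
    dh <- delta %*% t(p$Wh)
  }
  list(Wx = dWx, Wh = dWh, b = matrix(db, 1), Wo = dWo, bo = matrix(dbo, 1))
}

gru_init <- function(N, H, d)
  list(Wz = glorot(N, H), Uz = glorot(H, H), bz = matrix(0, 1, H),
       Wr = glorot(N, H), Ur = glorot(H, H), br = matrix(0, 1, H),
       Wn = glorot(N, H), Un = glorot(H, H), bn = matrix(0, 1, H),
       Wo = glorot(H, d), bo = matrix(0, 1, d))

gru_forward <- function(p, X3, dropout = 0, train = FALSE) {
  K <- dim(X3)[1]; B <- dim(X3)[3]; H <- ncol(p$Uz)
  X3 <- seq_input_dropout(X3, dropout, train)
  hs <- vector("list", B + 1); zc <- rc <- nc <- vector("list", B)
  hs[[1]] <- matrix(0, K, H)
  for (j in seq_len(B)) {
    x <- X3[, , j, drop = FALSE]; dim(x) <- dim(X3)[1:2]
    h0 <- hs[[j]]
    z <- sigmoid(sweep(x %*% p$Wz + h0 %*% p$Uz, 2, p$bz, "+"))
    r <- sigmoid(sweep(x %*% p$Wr + h0 %*% p$Ur, 2, p$br, "+"))
    n <- tanh(sweep(x %*% p$Wn + (r * h0) %*% p$Un, 2, p$bn, "+"))
    hs[[j + 1]] <- (1 - z) * h0 + z * n
    zc[[j]] <- z; rc[[j]] <- r; nc[[j]] <- n
  }
  hB <- hs[[B + 1]]
  Yh <- sweep(hB %*% p$Wo, 2, p$bo, "+")
  list(Yh = Yh, hs = hs, z = zc, r = rc, n = nc, hB = hB, M = NULL, X3 = X3, B = B)
}

gru_backward <- function(p, cache, dY) {
  B <- cache$B
  g <- lapply(p, function(x) x * 0)
  g$Wo <- crossprod(cache$hB, dY); g$bo <- matrix(colSums(dY), 1)
  dh <- dY %*% t(p$Wo)
  if (!is.null(cache$M)) dh <- dh * cache$M
  for (j in B:1) {
    x <- cache$X3[, , j, drop = FALSE]; dim(x) <- dim(cache$X3)[1:2]
    h0 <- cache$hs[[j]]; z <- cache$z[[j]]; r <- cache$r[[j]]; n <- cache$n[[j]]
    dn <- dh * z
    dz <- dh * (n - h0)
    dh0 <- dh * (1 - z)
    dan <- dn * (1 - n^2)
    g$Wn <- g$Wn + crossprod(x, dan)
    g$Un <- g$Un + crossprod(r * h0, dan)
    g$bn <- g$bn + matrix(colSums(dan), 1)
    drh <- dan %*% t(p$Un)
    dr <- drh * h0
    dh0 <- dh0 + drh * r
    daz <- dz * z * (1 - z)
    g$Wz <- g$Wz + crossprod(x, daz)
    g$Uz <- g$Uz + crossprod(h0, daz)
    g$bz <- g$bz + matrix(colSums(daz), 1)
    dh0 <- dh0 + daz %*% t(p$Uz)
    dar <- dr * r * (1 - r)
    g$Wr <- g$Wr + crossprod(x, dar)
    g$Ur <- g$Ur + crossprod(h0, dar)
    g$br <- g$br + matrix(colSums(dar), 1)
    dh0 <- dh0 + dar %*% t(p$Ur)
    dh <- dh0
  }
  g
}

lstm_init <- function(N, H, d)
  list(Wi = glorot(N, H), Ui = glorot(H, H), bi = matrix(0, 1, H),
       Wf = glorot(N, H), Uf = glorot(H, H), bf = matrix(1, 1, H),  # forget bias 1
       Wg = glorot(N, H), Ug = glorot(H, H), bg = matrix(0, 1, H),
       Wo_ = glorot(N, H), Uo_ = glorot(H, H), bo_ = matrix(0, 1, H),
       Wo = glorot(H, d), bo = matrix(0, 1, d))

lstm_forward <- function(p, X3, dropout = 0, train = FALSE) {
  K <- dim(X3)[1]; B <- dim(X3)[3]; H <- ncol(p$Ui)
  X3 <- seq_input_dropout(X3, dropout, train)
  hs <- cs <- vector("list", B + 1)
  ic <- fc <- gc <- oc <- vector("list", B)
  hs[[1]] <- cs[[1]] <- matrix(0, K, H)
  for (j in seq_len(B)) {
    x <- X3[, , j, drop = FALSE]; dim(x) <- dim(X3)[1:2]
    h0 <- hs[[j]]; c0 <- cs[[j]]
    i <- sigmoid(sweep(x %*% p$Wi + h0 %*% p$Ui, 2, p$bi, "+"))
    f <- sigmoid(sweep(x %*% p$Wf + h0 %*% p$Uf, 2, p$bf, "+"))
    g <- tanh(sweep(x %*% p$Wg + h0 %*% p$Ug, 2, p$bg, "+"))
    o <- sigmoid(sweep(x %*% p$Wo_ + h0 %*% p$Uo_, 2, p$bo_, "+"))
    cs[[j + 1]] <- f * c0 + i * g
    hs[[j + 1]] <- o * tanh(cs[[j + 1]])
    ic[[j]] <- i; fc[[j]] <- f; gc[[j]] <- g; oc[[j]] <- o
  }
  hB <- hs[[B + 1]]
  Yh <- sweep(hB %*% p$Wo, 2, p$bo, "+")
  list(Yh = Yh, hs = hs, cs = cs, i = ic, f = fc, g = gc, o = oc,
       hB = hB, M = NULL, X3 = X3, B = B)
}

lstm_backward <- function(p, cache, dY) {
  B <- cache$B
  gr <- lapply(p, function(x) x * 0)
  gr$Wo <- crossprod(cache$hB, dY); gr$bo <- matrix(colSums(dY), 1)
  dh <- dY %*% t(p$Wo)
  if (!is.null(cache$M)) dh <- dh * cache$M
  dc <- cache$cs[[B + 1]] * 0
  for (j in B:1) {
    x <- cache$X3[, , j, drop = FALSE]; dim(x) <- dim(cache$X3)[1:2]
    h0 <- cache$hs[[j]]; c0 <- cache$cs[[j]]; c1 <- cache$cs[[j + 1]]
    i <- cache$i[[j]]; f <- cache$f[[j]]; g <- cache$g[[j]]; o <- cache$o[[j]]
    tc <- tanh(c1)
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g; df <- dc * c0; dg <- dc * i
    dc0 <- dc * f
    dai <- di * i * (1 - i); daf <- df * f * (1 - f)
    dag <- dg * (1 - g^2);   dao <- do_ * o * (1 - o)
    gr$Wi <- gr$Wi + crossprod(x, dai);  gr$Ui <- gr$Ui + crossprod(h0, dai)
    gr$bi <- gr$bi + matrix(colSums(dai), 1)
    gr$Wf <- gr$Wf + crossprod(x, daf);  gr$Uf <- gr$Uf + crossprod(h0, daf)
    gr$bf <- gr$bf + matrix(colSums(daf), 1)
    gr$Wg <- gr$Wg + crossprod(x, dag);  gr$Ug <- gr$Ug + crossprod(h0, dag)
    gr$bg <- gr$bg + matrix(colSums(dag), 1)
    gr$Wo_ <- gr$Wo_ + crossprod(x, dao); gr$Uo_ <- gr$Uo_ + crossprod(h0, dao)
    gr$bo_ <- gr$bo_ + matrix(colSums(dao), 1)
    dh <- dai %*% t(p$Ui) + daf %*% t(p$Uf) + dag %*% t(p$Ug) + dao %*% t(p$Uo_)
    dc <- dc0
  }
  gr
}

net_funs <- list(
  feedforward = list(init = mlp_init, forward = mlp_forward, backward = mlp_backward),
  rnn = list(init = rnn_init, forward = rnn_forward, backward = rnn_backward),
  gru = list(init = gru_init, forward = gru_forward, backward = gru_backward),
  lstm = list(init = lstm_init, forward = lstm_forward, backward = lstm_backward))

net_loss_grad <- function(family, params, Xb, Yb, dropout, train = TRUE) {
  f <- net_funs[[family]]
  cache <- f$forward(params, Xb, dropout = dropout, train = train)
  resid <- cache$Yh - Yb
  n <- nrow(Yb)
  loss <- sum(resid^2) / n          # MSE summed over output dims
  grads <- f$backward(params, cache, 2 * resid / n)
  list(loss = loss, grads = grads)
}

slice_rows <- function(X, idx) {
  if (length(dim(X)) == 3) X[idx, , , drop = FALSE] else X[idx, , drop = FALSE]
}

train_net <- function(family, X, Y, units = 100, dropout = 0, epochs = 10,
                      lr = 3e-3, batch_size = 128, seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y) || !all(is.finite(Y))) stop_invalid_input("non-finite training data")
  K <- if (length(dim(X)) == 3) dim(X)[1] else nrow(X)
  nin <- if (length(dim(X)) == 3) dim(X)[2] else ncol(X)
  d <- ncol(Y)
  params <- net_funs[[family]]$init(nin, units, d)
  st <- adam_init(params)
  t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(K)
    losses <- c()
    for (start in seq(1, K, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, K)]
      lg <- net_loss_grad(family, params, slice_rows(X, idx),
                          Y[idx, , drop = FALSE], dropout)
      if (!is.finite(lg$loss))
        abort("training loss diverged (non-finite); lower the learning rate",
              class = "spikedecode_fit_failure")
      t <- t + 1
      upd <- adam_step(params, lg$grads, st, lr, t)
      params <- upd$params; st <- upd$st
      losses <- c(losses, lg$loss)
    }
    if (verbose) message(sprintf("[%s] epoch %d loss %.5f", family, ep, mean(losses)))
  }
  structure(list(family = family, params = params, units = units,
                 dropout = dropout, epochs = epochs, lr = lr,
                 batch_size = batch_size, d = d), class = "spikedecode_net")
}

#' @export
predict.spikedecode_net <- function(object, newdata, ...) {
  net_funs[[object$family]]$forward(object$params, newdata)$Yh
}

#' @export
print.spikedecode_net <- function(x, ...) {
  cat(sprintf("<%s net> %d units, dropout %g, %d epochs\n",
              x$family, x$units, x$dropout, x$epochs))
  invisible(x)
}
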