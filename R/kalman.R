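#' Build a kinematic state matrix from position or velocity
#'
#' The Kalman decoder's hidden state stacks position, velocity and
#' acceleration for every output axis (state dimension `s = 3*d`; 6 for 2-D
#' tasks). Missing derivative orders are obtained by finite differences on
#' the bin grid (central differences, one-sided at the ends); missing
#' integrals (position from velocity) by cumulative sums. Even when only
#' position or velocity is to be reported, carrying all kinematic orders in
#' the state improves prediction.
#'
#' @param outputs K x d matrix of the recorded output (position or velocity).
#' @param bin_size Bin width in seconds.
#' @param kind `"position"` or `"velocity"`: what `outputs` contains.
#' @return K x (3*d) matrix with columns position, velocity, acceleration
#'   (d columns each, in that order).
#' @export
kinematic_states <- function(outputs, bin_size, kind = c("position", "velocity")) {
  kind <- match.arg(kind)
  Y <- as.matrix(outputs)
  if (kind == "position") {
    pos <- Y
    vel <- apply(pos, 2, central_diff) / bin_size
  } else {
    vel <- Y
    pos <- apply(vel, 2, cumsum) * bin_size
  }
  acc <- apply(vel, 2, central_diff) / bin_size
  out <- cbind(pos, vel, acc)
  colnames(out) <- c(paste0("pos", seq_len(ncol(Y))), paste0("vel", seq_len(ncol(Y))),
                     paste0("acc", seq_len(ncol(Y))))
  out
}

central_diff <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d
}

#' Fit the linear-Gaussian Kalman decoding model
#'
#' Estimates the state-transition matrix `A` and its noise covariance `W`
#' by least squares on successive kinematic states, and the observation
#' matrix `H` (spike counts as a linear function of the state) and its noise
#' covariance `Q` from the same training data. A signed `lag` pairs the
#' counts at bin `t + lag` with the state at bin `t`. The training-set mean
#' state and state covariance are stored as the decoding prior.
#'
#' @param states K x s matrix of kinematic states (see [kinematic_states]).
#' @param observations K x N matrix of binned spike counts.
#' @param lag Signed integer bin offset between observations and states.
#' @param noise_scale Positive scalar multiplying `W` during decoding; 1
#'   gives the classical filter, and tuning it on a validation set trades
#'   smoothness against responsiveness.
#' @return Object of class `kalman_model` with `A`, `W`, `H`, `Q`,
#'   `noise_scale`, `lag`, `init_mean`, `init_cov`.
#' @export
kalman_fit <- function(states, observations, lag = 0L, noise_scale = 1) {
  X <- as.matrix(states); Z <- as.matrix(observations)
  if (nrow(X) != nrow(Z)) stop_invalid_input("states and observations row counts differ")
  if (noise_scale <= 0) stop_invalid_arg("`noise_scale` must be positive")
  s <- ncol(X)
  if (nrow(X) < s + 1) stop_insufficient("need more time bins than state dimensions")
  if (lag != 0) {
    K <- nrow(X)
    if (lag > 0) { X <- X[seq_len(K - lag), , drop = FALSE]
                   Z <- Z[(lag + 1):K, , drop = FALSE] }
    else         { X <- X[(-lag + 1):K, , drop = FALSE]
                   Z <- Z[seq_len(K + lag), , drop = FALSE] }
  }
  K <- nrow(X)
  X1 <- X[-K, , drop = FALSE]; X2 <- X[-1, , drop = FALSE]
  # affine fits (free intercept): equivalent to the centred-data
  # formulation, and required when states or counts are not zero-mean
  cfA <- qr.coef(qr(cbind(X1, 1)), X2)              # x_{t+1} ~ A x_t + a
  A <- t(cfA[seq_len(s), , drop = FALSE])
  a <- cfA[s + 1, ]
  resA <- X2 - cbind(X1, 1) %*% cfA
  W <- crossprod(resA) / (K - 1)
  cfH <- qr.coef(qr(cbind(X, 1)), Z)                # z_t ~ H x_t + b
  H <- t(cfH[seq_len(s), , drop = FALSE])
  b <- cfH[s + 1, ]
  resH <- Z - cbind(X, 1) %*% cfH
  Q <- crossprod(resH) / K
  structure(list(A = A, W = (W + t(W)) / 2, H = H, Q = (Q + t(Q)) / 2,
                 trans_offset = a, obs_offset = b,
                 noise_scale = noise_scale, lag = as.integer(lag),
                 init_mean = colMeans(X), init_cov = cov(X), s = s),
            class = "kalman_model")
}

#' Decode states from spike counts with a fitted Kalman model
#'
#' Runs the standard predict/update recursion with transition noise
#' `noise_scale * W`, starting from the stored training-set mean state and
#' state covariance. Covariances are symmetrised after every update and, if
#' numerical error produces a negative eigenvalue, clipped at zero with a
#' warning.
#'
#' @param model A fitted `kalman_model`.
#' @param observations K x N count matrix.
#' @param noise_scale Optional override of the stored transition-noise scale.
#' @param return_cov If `TRUE`, also return the K filtered covariances.
#' @return K x s matrix of filtered state means (attribute `"cov"` holds the
#'   covariance array when requested).
#' @export
kalman_decode <- function(model, observations, noise_scale = NULL, return_cov = FALSE) {
  Z <- as.matrix(observations)
  C <- noise_scale %||% model$noise_scale
  if (C <= 0) stop_invalid_arg("`noise_scale` must be positive")
  A <- model$A; W <- model$W * C; H <- model$H; Q <- model$Q
  s <- model$s; K <- nrow(Z)
  a <- model$trans_offset %||% numeric(s)
  b <- model$obs_offset %||% numeric(nrow(H))
  x <- model$init_mean
  P <- model$init_cov
  out <- matrix(0, K, s)
  covs <- if (return_cov) array(0, c(s, s, K)) else NULL
  clipped <- FALSE
  for (t in seq_len(K)) {
    xp <- drop(A %*% x) + a
    Pp <- A %*% P %*% t(A) + W
    S <- H %*% Pp %*% t(H) + Q
    Kg <- t(solve(S, H %*% Pp))            # Pp H' S^{-1}
    x <- xp + drop(Kg %*% (Z[t, ] - drop(H %*% xp) - b))
    P <- Pp - Kg %*% H %*% Pp
    P <- (P + t(P)) / 2
    ev <- eigen(P, symmetric = TRUE)
    if (any(ev$values < 0)) {
      clipped <- TRUE
      P <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    }
    out[t, ] <- x
    if (return_cov) covs[, , t] <- P
  }
  if (clipped) warn("filtered covariance lost positive semidefiniteness; eigenvalues clipped at 0")
  colnames(out) <- colnames(model$init_mean) %||% names(model$init_mean)
  if (return_cov) attr(out, "cov") <- covs
  out
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("<kalman_model> state dim %d, %d neurons, noise_scale %g, lag %d\n",
              x$s, nrow(x$H), x$noise_scale, x$lag))
  invisible(x)
}

#' @export
glance.kalman_model <- function(x, ...) {
  tibble::tibble(state_dim = x$s, n_neurons = nrow(x$H),
                 noise_scale = x$noise_scale, lag = x$lag)
}
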