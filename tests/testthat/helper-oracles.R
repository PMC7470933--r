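# Independent oracles used across tests. These deliberately re-derive the
# quantities by brute force (explicit normal equations, joint-Gaussian
# conditioning, exhaustive posterior enumeration) along code paths that
# share nothing with the package implementation.

# exact least squares through the explicit normal equations
ols_oracle <- function(X, Y) {
  Xa <- cbind(1, X)
  solve(t(Xa) %*% Xa, t(Xa) %*% as.matrix(Y))
}

random_stable_matrix <- function(s, radius = 0.9) {
  A <- matrix(rnorm(s * s), s, s)
  A * radius / max(Mod(eigen(A, only.values = TRUE)$values))
}

random_psd <- function(s, scale = 1) {
  M <- matrix(rnorm(s * s), s, s)
  crossprod(M) * scale / s + diag(1e-3, s)
}

# filtered means E[x_t | z_1..z_t] by conditioning the explicit joint
# Gaussian of (x_1..x_T, z_1..z_T); prior chain x_1 = A x_0 + w with
# x_0 ~ N(m0, P0), matching the decoder's predict-then-update convention
kalman_joint_oracle <- function(A, W, H, Q, m0, P0, Z) {
  T_ <- nrow(Z); s <- nrow(A); N <- nrow(H)
  mu <- vector("list", T_)
  P <- vector("list", T_)       # marginal covariances
  mu[[1]] <- drop(A %*% m0)
  P[[1]] <- A %*% P0 %*% t(A) + W
  for (t in 2:max(T_, 2)) {
    if (t > T_) break
    mu[[t]] <- drop(A %*% mu[[t - 1]])
    P[[t]] <- A %*% P[[t - 1]] %*% t(A) + W
  }
  cxx <- function(t, u) {      # Cov(x_t, x_u), t >= u
    M <- P[[u]]
    if (t > u) for (k in seq_len(t - u)) M <- A %*% M
    M
  }
  out <- matrix(0, T_, s)
  for (t in seq_len(T_)) {
    zmu <- unlist(lapply(seq_len(t), function(u) H %*% mu[[u]]))
    Czz <- matrix(0, t * N, t * N)
    Cxz <- matrix(0, s, t * N)
    for (u in seq_len(t)) for (v in seq_len(t)) {
      Cuv <- if (u >= v) cxx(u, v) else t(cxx(v, u))
      blk <- H %*% Cuv %*% t(H)
      if (u == v) blk <- blk + Q
      Czz[(u - 1) * N + 1:N, (v - 1) * N + 1:N] <- blk
    }
    for (v in seq_len(t)) {
      Ctv <- if (t >= v) cxx(t, v) else t(cxx(v, t))
      Cxz[, (v - 1) * N + 1:N] <- Ctv %*% t(H)
    }
    zvec <- as.vector(t(Z[seq_len(t), , drop = FALSE]))
    out[t, ] <- mu[[t]] + drop(Cxz %*% solve(Czz, zvec - zmu))
  }
  out
}

# exhaustive Naive Bayes posterior over grid cells via dpois products
nb_enum_oracle <- function(tuning, prior, counts) {
  G <- ncol(tuning)
  t(apply(counts, 1, function(n) {
    p <- vapply(seq_len(G), function(g)
      prod(dpois(n, tuning[, g])) * prior[g], numeric(1))
    p / sum(p)
  }))
}

make_linear_design <- function(K, P, d = 1, noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(K * P), K, P)
  W <- matrix(rnorm(P * d), P, d)
  intercept <- rnorm(d)
  Y <- X %*% W + matrix(intercept, K, d, byrow = TRUE) +
    matrix(rnorm(K * d, 0, noise), K, d)
  list(X = X, Y = Y, W = W, intercept = intercept)
}

random_binned <- function(n_bins = 20, N = 3, d = 2, bin_size = 0.05, seed = 1) {
  set.seed(seed)
  binned_dataset(matrix(rpois(n_bins * N, 2), n_bins, N),
                 matrix(rnorm(n_bins * d), n_bins, d), bin_size)
}
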