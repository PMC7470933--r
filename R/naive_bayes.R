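#' Sum spike counts over the lag window
#'
#' The Naive Bayes decoder sees, for each predictable output bin, the total
#' count of every neuron over the B-bin lag window (the same information
#' window the other decoders receive). The window duration `B * bin_size`
#' is the exposure time of the Poisson encoding model.
#'
#' @param data A [binned_dataset].
#' @param lags A [lag_spec].
#' @return List with `counts` (K x N summed counts), `Y` (K x d outputs),
#'   `row_to_bin`, and `window_s` (window duration in seconds).
#' @export
window_counts <- function(data, lags) {
  dm <- make_design_matrix(data, lags)
  N <- dm$n_neurons
  W <- matrix(0, nrow(dm$X), N)
  for (j in seq_len(lags$B))
    W <- W + dm$X[, (j - 1L) * N + seq_len(N), drop = FALSE]
  colnames(W) <- colnames(data$counts)
  list(counts = W, Y = dm$Y, row_to_bin = dm$row_to_bin,
       window_s = lags$B * data$bin_size)
}

make_grid <- function(Y, resolution) {
  d <- ncol(Y)
  if (is.null(resolution)) resolution <- if (d == 1) 100L else 30L
  resolution <- rep(as.integer(resolution), length.out = d)
  lo <- apply(Y, 2, min); hi <- apply(Y, 2, max)
  pad <- pmax(hi - lo, .Machine$double.eps) * 1e-9
  edges <- lapply(seq_len(d), function(k)
    seq(lo[k] - pad[k], hi[k] + pad[k], length.out = resolution[k] + 1))
  centers1 <- lapply(edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  centers <- as.matrix(expand.grid(centers1))       # G x d, dim 1 fastest
  colnames(centers) <- colnames(Y)
  list(edges = edges, centers = centers, resolution = resolution, d = d)
}

grid_cell_of <- function(grid, Y) {
  d <- grid$d
  idx1 <- vapply(seq_len(d), function(k) {
    i <- findInterval(Y[, k], grid$edges[[k]], rightmost.closed = TRUE)
    pmin(pmax(i, 1L), grid$resolution[k])
  }, integer(nrow(Y)))
  idx1 <- matrix(idx1, ncol = d)
  cell <- idx1[, 1]
  if (d > 1) for (k in 2:d) cell <- cell + (idx1[, k] - 1L) * prod(grid$resolution[1:(k - 1)])
  cell
}

# Gaussian smoothing of a per-cell quantity over the grid, bandwidth in cells.
grid_smooth <- function(v, grid, bandwidth) {
  if (bandwidth <= 0) return(v)
  sm <- v
  n_dims <- grid$d
  dim_v <- grid$resolution
  arr <- array(sm, dim = dim_v)
  for (k in seq_len(n_dims)) {
    n <- dim_v[k]
    kern <- exp(-0.5 * ((seq_len(2 * n - 1) - n) / bandwidth)^2)
    Kmat <- matrix(0, n, n)
    for (a in seq_len(n)) Kmat[a, ] <- kern[(n - a + 1):(2 * n - a)]
    Kmat <- Kmat / rowSums(Kmat)
    arr <- apply_along(arr, k, function(x) drop(Kmat %*% x))
  }
  as.vector(arr)
}

apply_along <- function(arr, k, f) {
  dims <- dim(arr) %||% length(arr)
  if (length(dims) == 1) return(f(arr))
  perm <- c(k, setdiff(seq_along(dims), k))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dims[k])
  m <- apply(m, 2, f)
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

#' Fit Poisson tuning curves and an occupancy prior for Bayesian decoding
#'
#' Discretises the output range onto a regular grid, estimates each
#' neuron's expected count per decoding window as the occupancy-normalised
#' mean count near each grid cell (Gaussian-smoothed over the grid), and
#' the prior as the smoothed occupancy distribution. Unvisited cells
#' receive a small count floor so that log-likelihoods stay finite.
#'
#' @param outputs K x d training outputs (d = 1 or 2).
#' @param counts K x N spike counts per decoding window (see
#'   [window_counts]).
#' @param grid_resolution Cells per output dimension (default 100 for 1-D,
#'   30 for 2-D).
#' @param smoothing_bandwidth Gaussian smoothing width in grid cells
#'   (default 1).
#' @param rate_floor Minimum expected count per window (default 0.01).
#' @return Object of class `naive_bayes_model`.
#' @export
nb_fit <- function(outputs, counts, grid_resolution = NULL,
                   smoothing_bandwidth = 1, rate_floor = 0.01) {
  Y <- as.matrix(outputs); Z <- as.matrix(counts)
  if (nrow(Y) == 0) stop_insufficient("empty training set")
  if (nrow(Y) != nrow(Z)) stop_invalid_input("outputs and counts row counts differ")
  if (ncol(Y) > 2) stop_invalid_arg("Naive Bayes decoding supports 1-D or 2-D outputs")
  grid <- make_grid(Y, grid_resolution)
  G <- nrow(grid$centers); N <- ncol(Z)
  cell <- grid_cell_of(grid, Y)
  occ <- tabulate(cell, nbins = G)
  sums <- matrix(0, N, G)
  cs <- rowsum(Z, cell, reorder = TRUE)       # cells x N (occupied only)
  sums[, as.integer(rownames(cs))] <- t(cs)
  occ_s <- grid_smooth(occ, grid, smoothing_bandwidth)
  tuning <- matrix(0, N, G)
  for (i in seq_len(N)) {
    num <- grid_smooth(sums[i, ], grid, smoothing_bandwidth)
    tuning[i, ] <- ifelse(occ_s > 0, num / pmax(occ_s, .Machine$double.eps), 0)
  }
  tuning <- pmax(tuning, rate_floor)
  prior <- occ_s + 1e-12
  prior <- prior / sum(prior)
  disp <- sqrt(mean(rowSums(apply(Y, 2, diff)^2)))   # per-bin displacement SD
  structure(list(grid = grid, tuning = tuning, prior = prior,
                 transition_bandwidth = disp, smoothing_bandwidth = smoothing_bandwidth,
                 rate_floor = rate_floor, n_neurons = N),
            class = "naive_bayes_model")
}

#' Decode outputs by maximum a posteriori grid search
#'
#' For each window, the log-posterior over grid cells combines the Poisson
#' log-likelihood of every neuron's count under its tuning curve — the
#' neurons' contributions add, by conditional independence — with the log
#' occupancy prior and, optionally, a Gaussian transition prior centred on
#' the previous decoded value. The prediction is the grid value at the
#' posterior maximum (ties broken toward the lowest grid index).
#'
#' @param model A fitted `naive_bayes_model`.
#' @param counts K x N window counts.
#' @param use_transition_prior Add the Gaussian transition term.
#' @param transition_bandwidth Transition SD in output units; defaults to
#'   the empirical per-bin displacement SD of the training outputs.
#' @param return_posterior If `TRUE`, attach the K x G normalised posterior
#'   (only valid without the sequential transition term).
#' @return K x d matrix of decoded outputs.
#' @export
nb_decode <- function(model, counts, use_transition_prior = FALSE,
                      transition_bandwidth = NULL, return_posterior = FALSE) {
  Z <- as.matrix(counts)
  if (ncol(Z) != model$n_neurons) stop_invalid_input("neuron count mismatch")
  logf <- log(model$tuning)                         # N x G
  ll <- Z %*% logf                                  # K x G
  ll <- sweep(ll, 2, colSums(model$tuning), "-")
  ll <- sweep(ll, 2, log(model$prior), "+")
  stopifnot(all(is.finite(ll)))
  G <- ncol(ll); K <- nrow(ll)
  centers <- model$grid$centers
  if (!use_transition_prior) {
    pick <- max.col(ll, ties.method = "first")
    out <- centers[pick, , drop = FALSE]
    if (return_posterior) {
      m <- apply(ll, 1, max)
      post <- exp(ll - m)
      attr(out, "posterior") <- post / rowSums(post)
    }
    return(out)
  }
  sigma <- transition_bandwidth %||% model$transition_bandwidth
  if (sigma < 0) stop_invalid_arg("`transition_bandwidth` must be non-negative")
  pick <- integer(K)
  pick[1] <- which.max(ll[1, ])
  for (t in 2:K) {
    prev <- centers[pick[t - 1], ]
    d2 <- rowSums(sweep(centers, 2, prev, "-")^2)
    lp <- if (sigma > 0) ll[t, ] - d2 / (2 * sigma^2) else ifelse(d2 == 0, ll[t, ], -Inf)
    pick[t] <- which.max(lp)
  }
  centers[pick, , drop = FALSE]
}

#' @export
print.naive_bayes_model <- function(x, ...) {
  cat(sprintf("<naive_bayes_model> %d neurons, grid %s (%d cells)\n",
              x$n_neurons, paste(x$grid$resolution, collapse = " x "),
              nrow(x$grid$centers)))
  invisible(x)
}

#' @export
glance.naive_bayes_model <- function(x, ...) {
  tibble::tibble(n_neurons = x$n_neurons, n_cells = nrow(x$grid$centers),
                 smoothing_bandwidth = x$smoothing_bandwidth,
                 transition_bandwidth = x$transition_bandwidth)
}
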