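#' @importFrom rlang abort warn .data
#' @importFrom stats approx sd predict rnorm runif rpois quantile var cov coef
#' @importFrom utils head tail
NULL

stop_invalid_arg <- function(msg) abort(msg, class = "spikedecode_invalid_argument")
stop_invalid_input <- function(msg) abort(msg, class = "spikedecode_invalid_input")
stop_insufficient <- function(msg) abort(msg, class = "spikedecode_insufficient_data")

#' Spike trains for a neural population
#'
#' Container for sorted spike event times, one vector per neuron, over a
#' recording of length `duration` seconds.
#'
#' @param spike_times List of numeric vectors of spike times in seconds,
#'   one element per neuron. Each vector must be sorted ascending with all
#'   times in `[0, duration)`.
#' @param duration Recording length in seconds.
#' @return An object of class `spike_data` with elements `spike_times`,
#'   `n_neurons`, and `duration`.
#' @examples
#' sd <- spike_data(list(c(0.02, 0.07, 0.12), numeric(0)), duration = 0.15)
#' sd$n_neurons
#' @export
spike_data <- function(spike_times, duration) {
  if (!is.list(spike_times) || length(spike_times) < 1)
    stop_invalid_input("`spike_times` must be a non-empty list of numeric vectors")
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop_invalid_arg("`duration` must be a positive scalar (seconds)")
  for (i in seq_along(spike_times)) {
    st <- spike_times[[i]]
    if (length(st) == 0) next
    if (!is.numeric(st)) stop_invalid_input("spike times must be numeric")
    if (is.unsorted(st)) stop_invalid_input(
      sprintf("spike times for neuron %d are not sorted ascending", i))
    if (min(st) < 0 || max(st) >= duration) stop_invalid_input(
      sprintf("spike times for neuron %d fall outside [0, duration)", i))
  }
  structure(
    list(spike_times = lapply(spike_times, as.numeric),
         n_neurons = length(spike_times),
         duration = as.numeric(duration)),
    class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d neurons, %.1f s, %d spikes\n",
              x$n_neurons, x$duration, sum(lengths(x$spike_times))))
  invisible(x)
}

#' Bin spike trains on a regular time grid
#'
#' Counts spikes in half-open bins `[t*R, (t+1)*R)` of width `R = bin_size`;
#' a spike exactly on a boundary belongs to the later bin. The trailing
#' partial bin (if `duration` is not a multiple of `bin_size`) is dropped,
#' so the grid has `floor(duration / bin_size)` bins.
#'
#' @param spikes A [spike_data] object.
#' @param bin_size Bin width R in seconds (positive).
#' @return Integer matrix of spike counts, rows = time bins, columns = neurons.
#' @examples
#' sd <- spike_data(list(c(0.02, 0.07, 0.12)), duration = 0.15)
#' bin_spikes(sd, 0.05)
#' @export
bin_spikes <- function(spikes, bin_size) {
  if (!inherits(spikes, "spike_data")) stop_invalid_input("`spikes` must be a spike_data object")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop_invalid_arg("`bin_size` must be a positive scalar")
  if (spikes$duration < bin_size)
    stop_invalid_arg("recording shorter than one bin")
  n_bins <- floor(spikes$duration / bin_size + 1e-9)
  counts <- matrix(0L, nrow = n_bins, ncol = spikes$n_neurons)
  for (i in seq_len(spikes$n_neurons)) {
    st <- spikes$spike_times[[i]]
    if (length(st) == 0) next
    idx <- floor(st / bin_size) + 1L
    idx <- idx[idx <= n_bins]          # drop spikes in the trailing remainder
    if (length(idx)) counts[, i] <- counts[, i] + tabulate(idx, nbins = n_bins)
  }
  colnames(counts) <- paste0("n", seq_len(spikes$n_neurons))
  counts
}

#' Bin time-stamped output samples on a regular time grid
#'
#' Each bin holds the arithmetic mean of the output samples whose timestamps
#' fall in that half-open bin. Bins containing no samples are filled by
#' linear interpolation between neighbouring bin values; leading/trailing
#' gaps are held at the nearest observed value.
#'
#' @param times Numeric vector of sample times in seconds.
#' @param values Numeric vector or matrix (samples x d) of output values.
#' @param bin_size Bin width in seconds.
#' @param duration Recording length in seconds; the grid has
#'   `floor(duration / bin_size)` bins, matching [bin_spikes].
#' @return Numeric matrix, rows = time bins, columns = output dimensions.
#' @export
bin_output <- function(times, values, bin_size, duration) {
  if (length(times) == 0) stop_invalid_input("no output samples supplied")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop_invalid_arg("`bin_size` must be a positive scalar")
  values <- as.matrix(values)
  if (nrow(values) != length(times))
    stop_invalid_input("`times` and `values` lengths differ")
  n_bins <- floor(duration / bin_size + 1e-9)
  if (n_bins < 1) stop_invalid_arg("recording shorter than one bin")
  idx <- floor(times / bin_size) + 1L
  keep <- idx >= 1L & idx <= n_bins
  idx <- idx[keep]
  if (length(idx) == 0) stop_invalid_input("no output samples fall on the bin grid")
  vals <- values[keep, , drop = FALSE]
  d <- ncol(vals)
  out <- matrix(NA_real_, n_bins, d)
  cnt <- tabulate(idx, nbins = n_bins)
  for (j in seq_len(d)) {
    s <- rowsum(vals[, j], idx, reorder = TRUE)
    out[as.integer(rownames(s)), j] <- s / cnt[cnt > 0]
  }
  filled <- which(cnt > 0)
  if (length(filled) < n_bins) {
    for (j in seq_len(d)) {
      out[, j] <- approx(x = filled, y = out[filled, j], xout = seq_len(n_bins),
                         method = "linear", rule = 2)$y
    }
  }
  colnames(out) <- colnames(values) %||% paste0("out", seq_len(d))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aligned binned spike counts and outputs
#'
#' Couples a spike-count matrix and an output matrix sharing the same time
#' grid of width `bin_size`.
#'
#' @param counts Non-negative integer matrix, bins x neurons.
#' @param outputs Numeric matrix, bins x output dimensions (same row count).
#' @param bin_size Bin width in seconds.
#' @return An object of class `binned_dataset`.
#' @export
binned_dataset <- function(counts, outputs, bin_size) {
  counts <- as.matrix(counts)
  outputs <- as.matrix(outputs)
  if (nrow(counts) != nrow(outputs))
    stop_invalid_input("`counts` and `outputs` must have the same number of time bins")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid_input("`counts` must be non-negative integers")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop_invalid_arg("`bin_size` must be positive")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("n", seq_len(ncol(counts)))
  if (is.null(colnames(outputs))) colnames(outputs) <- paste0("out", seq_len(ncol(outputs)))
  structure(list(counts = counts, outputs = outputs, bin_size = as.numeric(bin_size)),
            class = "binned_dataset")
}

#' Bin a spike_data object and output samples together
#'
#' Convenience wrapper running [bin_spikes] and [bin_output] on the same
#' grid and returning a [binned_dataset].
#'
#' @inheritParams bin_spikes
#' @inheritParams bin_output
#' @return A [binned_dataset].
#' @export
bin_dataset <- function(spikes, times, values, bin_size) {
  counts <- bin_spikes(spikes, bin_size)
  outputs <- bin_output(times, values, bin_size, spikes$duration)
  binned_dataset(counts, outputs, bin_size)
}

#' @export
print.binned_dataset <- function(x, ...) {
  cat(sprintf("<binned_dataset> %d bins x %d neurons, %d output dim(s), R = %g s\n",
              nrow(x$counts), ncol(x$counts), ncol(x$outputs), x$bin_size))
  invisible(x)
}

#' @export
as_tibble.binned_dataset <- function(x, ...) {
  tibble::as_tibble(cbind(
    data.frame(bin = seq_len(nrow(x$counts)),
               time = (seq_len(nrow(x$counts)) - 0.5) * x$bin_size),
    as.data.frame(x$counts), as.data.frame(x$outputs)))
}

#' Lag window specification
#'
#' Defines which bins of neural activity predict a given output bin: the
#' `bins_before` preceding bins, optionally the concurrent bin
#' (`bins_current` 0 or 1), and the `bins_after` following bins. The window
#' length is `B = bins_before + bins_current + bins_after`.
#'
#' @param bins_before Non-negative count of preceding bins.
#' @param bins_current 0 or 1: include the concurrent bin.
#' @param bins_after Non-negative count of following bins.
#' @return An object of class `lag_spec` with fields `bins_before`,
#'   `bins_current`, `bins_after`, `B`, and `offsets` (signed bin offsets in
#'   window order).
#' @examples
#' lag_spec(bins_before = 13, bins_current = 1, bins_after = 0)  # B = 14
#' lag_spec(bins_before = 4, bins_current = 1, bins_after = 5)   # B = 10
#' @export
lag_spec <- function(bins_before = 0L, bins_current = 1L, bins_after = 0L) {
  for (v in list(bins_before, bins_after))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop_invalid_arg("`bins_before`/`bins_after` must be non-negative integers")
  if (!bins_current %in% c(0, 1)) stop_invalid_arg("`bins_current` must be 0 or 1")
  B <- bins_before + bins_current + bins_after
  if (B < 1) stop_invalid_arg("lag window must contain at least one bin")
  offsets <- c(if (bins_before > 0) seq(-bins_before, -1),
               if (bins_current == 1) 0L,
               if (bins_after > 0) seq(1, bins_after))
  structure(list(bins_before = as.integer(bins_before),
                 bins_current = as.integer(bins_current),
                 bins_after = as.integer(bins_after),
                 B = as.integer(B), offsets = as.integer(offsets)),
            class = "lag_spec")
}

#' @export
print.lag_spec <- function(x, ...) {
  cat(sprintf("<lag_spec> B = %d (%d before, %d current, %d after)\n",
              x$B, x$bins_before, x$bins_current, x$bins_after))
  invisible(x)
}

check_window <- function(data, lags) {
  n_bins <- nrow(data$counts)
  if (n_bins <= lags$bins_before + lags$bins_after)
    stop_invalid_arg("lag window longer than the recording")
  n_bins
}

#' Flat lagged design matrix for non-recurrent decoders
#'
#' Builds the K x (N*B) covariate matrix in which row k concatenates the
#' spike counts of all N neurons over the B-bin lag window around output bin
#' `row_to_bin[k]`. The first `bins_before` and last `bins_after` output
#' bins are excluded, so `K = n_bins - bins_before - bins_after`. Columns
#' are ordered lag-major: all neurons at the earliest lag first, then all
#' neurons at the next lag, and so on.
#'
#' @param data A [binned_dataset].
#' @param lags A [lag_spec].
#' @return An object of class `design_matrix`: list with `X` (K x N*B), `Y`
#'   (K x d), `row_to_bin` (integer vector), `lags`, and `n_neurons`.
#' @export
make_design_matrix <- function(data, lags) {
  n_bins <- check_window(data, lags)
  N <- ncol(data$counts)
  K <- n_bins - lags$bins_before - lags$bins_after
  rows <- seq_len(K) + lags$bins_before
  X <- matrix(0, K, N * lags$B)
  for (j in seq_len(lags$B)) {
    off <- lags$offsets[j]
    X[, (j - 1L) * N + seq_len(N)] <- data$counts[rows + off, , drop = FALSE]
  }
  colnames(X) <- as.vector(vapply(lags$offsets, function(o)
    paste0(colnames(data$counts), "_lag", o), character(N)))
  structure(list(X = X, Y = data$outputs[rows, , drop = FALSE],
                 row_to_bin = rows, lags = lags, n_neurons = N),
            class = "design_matrix")
}

#' Sequence tensor for recurrent decoders
#'
#' Builds the K x N x B array in which `X3[k, i, j]` is the count of neuron
#' i at bin `row_to_bin[k] + offsets[j]`. Flattening the last two axes
#' (neuron index fastest) reproduces [make_design_matrix] exactly.
#'
#' @inheritParams make_design_matrix
#' @return An object of class `sequence_tensor`: list with `X3` (K x N x B),
#'   `Y`, `row_to_bin`, `lags`, `n_neurons`.
#' @export
make_sequence_tensor <- function(data, lags) {
  n_bins <- check_window(data, lags)
  N <- ncol(data$counts)
  K <- n_bins - lags$bins_before - lags$bins_after
  rows <- seq_len(K) + lags$bins_before
  X3 <- array(0, dim = c(K, N, lags$B))
  for (j in seq_len(lags$B))
    X3[, , j] <- data$counts[rows + lags$offsets[j], , drop = FALSE]
  structure(list(X3 = X3, Y = data$outputs[rows, , drop = FALSE],
                 row_to_bin = rows, lags = lags, n_neurons = N),
            class = "sequence_tensor")
}

#' Flatten a sequence tensor to the design-matrix layout
#'
#' @param tensor A `sequence_tensor`.
#' @return The K x (N*B) matrix equal to `make_design_matrix(...)$X`.
#' @export
flatten_tensor <- function(tensor) {
  d <- dim(tensor$X3)
  matrix(tensor$X3, nrow = d[1], ncol = d[2] * d[3])
}

#' Column scaler fitted on training rows
#'
#' Learns per-column location/scale from training rows only; the stored
#' parameters are then applied unchanged to validation or test rows
#' ([apply_scaler]) and inverted to return predictions to original units
#' ([invert_scaler]).
#'
#' @param x Numeric matrix of training rows.
#' @param mode `"zscore"` (center and scale to unit SD), `"center"` (subtract
#'   the column mean), or `"none"`.
#' @return An object of class `scaler`.
#' @export
fit_scaler <- function(x, mode = c("zscore", "center", "none")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  ctr <- if (mode == "none") rep(0, ncol(x)) else colMeans(x)
  scl <- rep(1, ncol(x))
  if (mode == "zscore") {
    scl <- apply(x, 2, sd)
    if (any(bad <- !is.finite(scl) | scl == 0)) {
      warn(sprintf("%d zero-variance column(s); scale clamped to 1", sum(bad)))
      scl[bad] <- 1
    }
  }
  structure(list(mode = mode, center = ctr, scale = scl), class = "scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$scale, "*"), 2, scaler$center, "+")
}
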