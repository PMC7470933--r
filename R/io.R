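# Readers and writers for the two on-disk formats: delimited text (a spike
# events file with columns neuron_id,time_s and an outputs file with
# columns time_s,out1..outd) and HDF5 (per-neuron spike-time vectors or a
# counts matrix, plus outputs with a time vector and bin-size metadata).

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    abort("HDF5 support requires the 'rhdf5' package", class = "spikedecode_invalid_argument")
}

#' Read spike events from delimited text
#'
#' Expects columns `neuron_id` (integer, 1-based) and `time_s`.
#'
#' @param path CSV file path.
#' @param duration Recording length in seconds; defaults to just past the
#'   last spike.
#' @param n_neurons Population size; defaults to the largest id seen.
#' @return A [spike_data] object.
#' @export
read_spike_events_csv <- function(path, duration = NULL, n_neurons = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    neuron_id = readr::col_integer(), time_s = readr::col_double()))
  if (!all(c("neuron_id", "time_s") %in% names(df)))
    stop_invalid_input("spike events file needs columns neuron_id,time_s")
  n <- n_neurons %||% max(df$neuron_id)
  dur <- duration %||% (max(df$time_s) + 1e-6)
  lst <- lapply(seq_len(n), function(i) sort(df$time_s[df$neuron_id == i]))
  spike_data(lst, dur)
}

#' Write spike events to delimited text
#' @param spikes A [spike_data] object.
#' @param path Output CSV path.
#' @export
write_spike_events_csv <- function(spikes, path) {
  df <- tibble::tibble(
    neuron_id = rep.int(seq_len(spikes$n_neurons), lengths(spikes$spike_times)),
    time_s = unlist(spikes$spike_times, use.names = FALSE))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read time-stamped outputs from delimited text
#'
#' Expects a `time_s` column followed by one column per output dimension.
#'
#' @param path CSV file path.
#' @return List with `times` and `values` (matrix).
#' @export
read_outputs_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  if (!"time_s" %in% names(df)) stop_invalid_input("outputs file needs a time_s column")
  list(times = df$time_s,
       values = as.matrix(df[setdiff(names(df), "time_s")]))
}

#' Write time-stamped outputs to delimited text
#' @param times Sample times (seconds).
#' @param values Vector or matrix of output samples.
#' @param path Output CSV path.
#' @export
write_outputs_csv <- function(times, values, path) {
  values <- as.matrix(values)
  colnames(values) <- colnames(values) %||% paste0("out", seq_len(ncol(values)))
  readr::write_csv(tibble::as_tibble(cbind(time_s = times, values)), path)
  invisible(path)
}

#' Write a binned dataset to HDF5
#'
#' Layout: datasets `counts` (bins x neurons) and `outputs` (bins x d),
#' dataset `bin_size`, and optional `lags` (bins_before, bins_current,
#' bins_after).
#'
#' @param data A [binned_dataset].
#' @param path Output `.h5` path (overwritten).
#' @param lags Optional [lag_spec] stored as metadata.
#' @export
write_binned_h5 <- function(data, path, lags = NULL) {
  need_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(unname(data$counts), path, "counts")
  rhdf5::h5write(unname(data$outputs), path, "outputs")
  rhdf5::h5write(data$bin_size, path, "bin_size")
  if (!is.null(lags))
    rhdf5::h5write(c(lags$bins_before, lags$bins_current, lags$bins_after),
                   path, "lags")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a binned dataset from HDF5
#' @param path `.h5` file written by [write_binned_h5].
#' @return A [binned_dataset]; any stored [lag_spec] is attached as
#'   attribute `"lags"`.
#' @export
read_binned_h5 <- function(path) {
  need_rhdf5()
  counts <- rhdf5::h5read(path, "counts")
  outputs <- rhdf5::h5read(path, "outputs")
  bin_size <- as.numeric(rhdf5::h5read(path, "bin_size"))
  nm <- rhdf5::h5ls(path, recursive = FALSE)$name
  out <- binned_dataset(counts, outputs, bin_size)
  if ("lags" %in% nm) {
    lg <- as.integer(rhdf5::h5read(path, "lags"))
    attr(out, "lags") <- lag_spec(lg[1], lg[2], lg[3])
  }
  rhdf5::h5closeAll()
  out
}

#' Write a synthetic dataset (with ground truth) to HDF5
#'
#' Layout: groups `spikes` (per-neuron time vectors `t0001`, ...),
#' `outputs` (`time`, `values`), `ground_truth` (numeric generative
#' parameters), plus `duration` and `bin_size`.
#'
#' @param sim A `synthetic_dataset` from [simulate_cortical] or
#'   [simulate_hippocampal].
#' @param path Output `.h5` path (overwritten).
#' @export
write_synthetic_h5 <- function(sim, path) {
  need_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "spikes")
  for (i in seq_len(sim$spikes$n_neurons))
    rhdf5::h5write(sim$spikes$spike_times[[i]], path, sprintf("spikes/t%04d", i))
  rhdf5::h5createGroup(path, "outputs")
  rhdf5::h5write(sim$output_times, path, "outputs/time")
  rhdf5::h5write(unname(sim$output_values), path, "outputs/values")
  rhdf5::h5write(sim$spikes$duration, path, "duration")
  rhdf5::h5write(sim$binned$bin_size, path, "bin_size")
  rhdf5::h5createGroup(path, "ground_truth")
  gt <- sim$ground_truth
  for (nm in names(gt)) {
    v <- gt[[nm]]
    if (is.numeric(v)) rhdf5::h5write(unname(v), path, paste0("ground_truth/", nm))
  }
  rhdf5::h5write(gt$mode, path, "ground_truth/mode_name")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a synthetic dataset written by [write_synthetic_h5]
#' @param path `.h5` file path.
#' @return List with `spikes`, `output_times`, `output_values`, `binned`,
#'   and the numeric `ground_truth` entries.
#' @export
read_synthetic_h5 <- function(path) {
  need_rhdf5()
  ls <- rhdf5::h5ls(path)
  spike_names <- sort(ls$name[ls$group == "/spikes"])
  duration <- as.numeric(rhdf5::h5read(path, "duration"))
  bin_size <- as.numeric(rhdf5::h5read(path, "bin_size"))
  st <- lapply(spike_names, function(nm) as.numeric(rhdf5::h5read(path, paste0("spikes/", nm))))
  spikes <- spike_data(st, duration)
  times <- as.numeric(rhdf5::h5read(path, "outputs/time"))
  values <- as.matrix(rhdf5::h5read(path, "outputs/values"))
  gt_names <- ls$name[ls$group == "/ground_truth"]
  gt <- lapply(gt_names, function(nm) rhdf5::h5read(path, paste0("ground_truth/", nm)))
  names(gt) <- gt_names
  rhdf5::h5closeAll()
  list(spikes = spikes, output_times = times, output_values = values,
       binned = bin_dataset(spikes, times, values, bin_size),
       ground_truth = gt)
}
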