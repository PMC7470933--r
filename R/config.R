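# Run configuration: YAML/JSON schema validation and the end-to-end
# pipeline entry point used by the command-line script.

config_schema <- function() {
  list(
    data = c("path", "format", "simulation"),
    simulation = c("mode", "n_neurons", "duration", "bin_size", "tuning_depth",
                   "mean_rate", "median_rate", "field_width", "seed"),
    bin_size = NULL, output_kind = NULL, decoders = NULL, folds = NULL,
    budget = NULL, strategy = NULL, seed = NULL, output_dir = NULL,
    stacker = NULL, use_transition_prior = NULL,
    lags = c("bins_before", "bins_current", "bins_after"),
    lags_overrides = NA)   # NA: free-form named list of lag specs
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    abort(sprintf("unknown configuration key(s) in %s: %s", where,
                  paste(bad, collapse = ", ")),
          class = "spikedecode_config_error")
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration, rejects unknown keys (naming the
#' offender), fills defaults, and returns the resolved configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config` with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), class = "spikedecode_config_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  schema <- config_schema()
  check_keys(cfg, names(schema), "top level")
  for (k in names(schema)) {
    allowed <- schema[[k]]
    if (!is.null(allowed) && !anyNA(allowed) && !is.null(cfg[[k]]))
      check_keys(cfg[[k]], allowed, k)
  }
  if (is.null(cfg$data))
    abort("config needs a `data` block (path or simulation)", class = "spikedecode_config_error")
  if (!is.null(cfg$data$simulation)) check_keys(cfg$data$simulation,
                                                config_schema()$simulation, "data.simulation")
  defaults <- list(bin_size = 0.05, output_kind = "velocity",
                   decoders = c("wiener", "feedforward"), folds = 10L,
                   budget = 1L, strategy = "bayesian", seed = 1L,
                   output_dir = "spikedecode_results", stacker = "feedforward",
                   use_transition_prior = TRUE,
                   lags = list(bins_before = 5L, bins_current = 1L, bins_after = 0L))
  cfg <- utils::modifyList(defaults, cfg)
  for (k in c("folds", "budget", "seed"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1)
      abort(sprintf("configuration key `%s` must be a positive number", k),
            class = "spikedecode_config_error")
  structure(cfg, class = "run_config")
}

resolve_dataset <- function(cfg) {
  if (!is.null(cfg$data$simulation)) {
    sim <- cfg$data$simulation
    mode <- sim$mode %||% "cortical"
    args <- sim[setdiff(names(sim), "mode")]
    args$seed <- args$seed %||% cfg$seed
    gen <- switch(mode,
      cortical = simulate_cortical,
      hippocampal = simulate_hippocampal,
      abort(sprintf("unknown simulation mode '%s'", mode),
            class = "spikedecode_config_error"))
    do.call(gen, args)$binned
  } else {
    path <- cfg$data$path
    fmt <- cfg$data$format %||% if (grepl("\\.h5$", path)) "h5" else "csv"
    if (fmt == "h5") read_binned_h5(path)
    else {
      spikes <- read_spike_events_csv(path)
      out <- read_outputs_csv(cfg$data$outputs_path %||% sub("\\.csv$", "_outputs.csv", path))
      bin_dataset(spikes, out$times, out$values, cfg$bin_size)
    }
  }
}

#' Run the full decoding pipeline from a configuration
#'
#' Resolves the dataset (reading it or simulating it), runs
#' [run_comparison], and writes `config.resolved.yaml`, `report.json`
#' (fold-level and aggregate scores) and `log.txt` into the output
#' directory.
#'
#' @param config A `run_config` from [load_config], or a path to one.
#' @return The `decoder_comparison` report, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("spikedecode run started %s", format(Sys.time()))
  data <- resolve_dataset(config)
  log_line("dataset: %d bins x %d neurons, bin size %g s",
           nrow(data$counts), ncol(data$counts), data$bin_size)
  lg <- config$lags
  lags <- lag_spec(lg$bins_before, lg$bins_current, lg$bins_after)
  over <- lapply(config$lags_overrides %||% list(), function(l)
    lag_spec(l$bins_before %||% 0L, l$bins_current %||% 1L, l$bins_after %||% 0L))
  report <- run_comparison(
    data, decoders = unlist(config$decoders), lags = lags,
    lags_overrides = over, folds = config$folds, budget = config$budget,
    strategy = config$strategy, output_kind = config$output_kind,
    stacker = config$stacker, use_transition_prior = config$use_transition_prior,
    seed = as.integer(config$seed))
  for (i in seq_len(nrow(report)))
    log_line("fold %d decoder %-14s R2 %.4f", report$fold[i], report$decoder[i],
             report$r2[i])
  yaml::write_yaml(unclass(config), file.path(config$output_dir, "config.resolved.yaml"))
  write_report_json(report, file.path(config$output_dir, "report.json"))
  if (requireNamespace("rhdf5", quietly = TRUE)) {
    write_predictions_h5(report, file.path(config$output_dir, "predictions.h5"))
    log_line("wrote predictions.h5")
  }
  log_line("run finished %s", format(Sys.time()))
  invisible(report)
}

#' Serialise a decoder comparison to JSON
#'
#' @param report A `decoder_comparison`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  summary <- glance(report)
  folds <- tidy(report)
  jsonlite::write_json(
    list(summary = summary, folds = folds,
         seed = attr(report, "seed") %||% NA_integer_),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the per-fold test predictions of a comparison to HDF5
#'
#' Layout: one group per decoder, one subgroup per fold holding `bins`
#' (original time-bin indices), `truth`, and `pred`. Every score in
#' `report.json` is recomputable from these arrays.
#'
#' @param report A `decoder_comparison` with stored predictions.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_predictions_h5 <- function(report, path) {
  need_rhdf5()
  preds <- attr(report, "predictions")
  if (is.null(preds)) stop_invalid_input("report has no stored predictions")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (dec in names(preds)) {
    rhdf5::h5createGroup(path, dec)
    for (f in seq_along(preds[[dec]])) {
      g <- sprintf("%s/fold%02d", dec, f)
      rhdf5::h5createGroup(path, g)
      p <- preds[[dec]][[f]]
      rhdf5::h5write(p$bins, path, paste0(g, "/bins"))
      rhdf5::h5write(unname(p$truth), path, paste0(g, "/truth"))
      rhdf5::h5write(unname(p$pred), path, paste0(g, "/pred"))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Command-line entry point
#'
#' Implements the `spikedecode` subcommands: `run` (full pipeline from a
#' config file), `simulate` (write a synthetic dataset to HDF5 or CSV),
#' `score` (R-squared between two CSV files of truth and predictions), and
#' `sweep` (feedforward units x dropout sensitivity surface on simulated
#' data). Exit codes: 0 success, 2 configuration error, 3 fit failure.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code.
#' @export
main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: spikedecode <run|simulate|score|sweep> [options]"
  if (length(argv) < 1) { message(usage); return(2L) }
  cmd <- argv[1]; rest <- argv[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
  }
  code <- tryCatch({
    switch(cmd,
      run = { run_pipeline(getopt("--config", "run.yaml")); 0L },
      simulate = {
        mode <- getopt("--mode", "cortical")
        seed <- as.integer(getopt("--seed", "1"))
        out <- getopt("--out", "data.h5")
        sim <- switch(mode,
          cortical = simulate_cortical(seed = seed),
          hippocampal = simulate_hippocampal(seed = seed),
          abort(sprintf("unknown mode '%s'", mode), class = "spikedecode_config_error"))
        if (grepl("\\.h5$", out)) write_synthetic_h5(sim, out)
        else {
          write_spike_events_csv(sim$spikes, out)
          write_outputs_csv(sim$output_times, sim$output_values,
                            sub("\\.csv$", "_outputs.csv", out))
        }
        message("wrote ", out); 0L
      },
      score = {
        truth <- as.matrix(readr::read_csv(getopt("--truth"),
                                           col_types = readr::cols()))
        pred <- as.matrix(readr::read_csv(getopt("--pred"),
                                          col_types = readr::cols()))
        cat(sprintf("R2 = %.6f\n", r2_score(truth, pred))); 0L
      },
      sweep = {
        seed <- as.integer(getopt("--seed", "1"))
        sim <- simulate_cortical(seed = seed)
        dm <- make_design_matrix(sim$binned, lag_spec(5, 1, 0))
        K <- nrow(dm$X); tr <- seq_len(floor(0.8 * K)); te <- (floor(0.8 * K) + 1):K
        xsc <- fit_scaler(dm$X[tr, ], "zscore")
        surf <- sweep_feedforward(
          apply_scaler(xsc, dm$X[tr, ]), dm$Y[tr, ],
          apply_scaler(xsc, dm$X[te, ]), dm$Y[te, ],
          units = as.integer(strsplit(getopt("--units", "100,300"), ",")[[1]]),
          dropouts = as.numeric(strsplit(getopt("--dropouts", "0,0.2"), ",")[[1]]),
          seed = seed)
        readr::write_csv(surf, getopt("--out", "sweep.csv")); 0L
      },
      { message(usage); 2L })
  },
  spikedecode_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  spikedecode_invalid_argument = function(e) { message("config error: ", conditionMessage(e)); 2L },
  spikedecode_fit_failure = function(e) { message("fit failure: ", conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 3L })
  code
}
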