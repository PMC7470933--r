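# Uniform save/load facade for fitted decoders. Coefficient-based models
# (Wiener filter/cascade, Kalman, Naive Bayes) additionally export to
# plain JSON for inspection and interoperability; learned decoders use
# R's native serialisation, with the boosted-tree booster converted to
# its backend-native raw bytes so the file survives across sessions.

#' Save and load fitted decoders
#'
#' `save_decoder()` writes any fitted decoder (`wiener_filter`,
#' `wiener_cascade`, `kalman_model`, `naive_bayes_model`,
#' `learned_decoder`, `ensemble_model`, or a raw network) to disk;
#' `load_decoder()` restores it. Boosted-tree models are stored as
#' backend-native raw bytes inside the file.
#'
#' @param object A fitted decoder.
#' @param path Output file path (`.rds`).
#' @return `save_decoder` returns `path` invisibly; `load_decoder` the
#'   restored decoder.
#' @export
save_decoder <- function(object, path) {
  if (inherits(object, "learned_decoder") &&
      object$spec$family == "boosted_trees") {
    object$models <- lapply(object$models, xgboost::xgb.save.raw)
    attr(object, "xgb_raw") <- TRUE
  }
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  object <- readRDS(path)
  if (isTRUE(attr(object, "xgb_raw"))) {
    object$models <- lapply(object$models, xgboost::xgb.load.raw)
    attr(object, "xgb_raw") <- NULL
  }
  object
}

#' Export a coefficient-based decoder to JSON
#'
#' Writes the numeric content of a Wiener filter, Wiener cascade, Kalman
#' model, or Naive Bayes model (coefficient arrays plus metadata) as
#' plain JSON readable by any language.
#'
#' @param object A `wiener_filter`, `wiener_cascade`, `kalman_model`, or
#'   `naive_bayes_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
export_decoder_json <- function(object, path) {
  payload <- if (inherits(object, "wiener_filter")) {
    list(type = "wiener_filter", weights = object$weights, ridge = object$ridge)
  } else if (inherits(object, "wiener_cascade")) {
    list(type = "wiener_cascade", degree = object$degree,
         linear_weights = lapply(object$linear, function(l) l$weights),
         poly_coeffs = object$poly_coeffs)
  } else if (inherits(object, "kalman_model")) {
    list(type = "kalman_model", A = object$A, W = object$W, H = object$H,
         Q = object$Q, trans_offset = object$trans_offset,
         obs_offset = object$obs_offset, noise_scale = object$noise_scale,
         lag = object$lag, init_mean = object$init_mean,
         init_cov = object$init_cov)
  } else if (inherits(object, "naive_bayes_model")) {
    list(type = "naive_bayes_model", tuning = object$tuning,
         prior = object$prior, grid_centers = object$grid$centers,
         grid_resolution = object$grid$resolution,
         transition_bandwidth = object$transition_bandwidth,
         smoothing_bandwidth = object$smoothing_bandwidth,
         rate_floor = object$rate_floor)
  } else {
    stop_invalid_arg("JSON export supports the coefficient-based decoders only")
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
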