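#' Stacked ensemble over first-tier decoder predictions
#'
#' Fits a second-tier model that maps the concatenated predictions of the
#' first-tier (base) decoders onto the true outputs. The canonical
#' configuration stacks the eight non-state-space decoders (Wiener filter
#' and cascade, SVR, boosted trees, feedforward, RNN, GRU, LSTM); the
#' Kalman filter and Naive Bayes decoders are excluded because their
#' input/output formats differ. Base predictions must come from rows the
#' base decoders did not train on (e.g. each fold's validation partition),
#' otherwise the stacker learns the bases' overfitting.
#'
#' @param base_predictions K x (m*d) matrix: the m base decoders'
#'   predictions, d output columns per base, or a named list of K x d
#'   matrices.
#' @param Y K x d true outputs aligned row-wise.
#' @param stacker `"feedforward"` (default, a small two-hidden-layer
#'   network) or `"linear"` (least squares; its training R-squared can
#'   never fall below any single base's).
#' @param units,epochs,lr Feedforward stacker hyperparameters.
#' @param seed Integer seed for the feedforward stacker.
#' @return Object of class `ensemble_model`.
#' @export
ensemble_fit <- function(base_predictions, Y, stacker = c("feedforward", "linear"),
                         units = 32, epochs = 30, lr = 5e-3, seed = NULL) {
  stacker <- match.arg(stacker)
  if (is.list(base_predictions) && !is.matrix(base_predictions)) {
    base_names <- names(base_predictions) %||% paste0("base", seq_along(base_predictions))
    base_predictions <- do.call(cbind, base_predictions)
  } else base_names <- NULL
  P <- as.matrix(base_predictions); Y <- as.matrix(Y)
  if (nrow(P) != nrow(Y)) stop_invalid_input("base predictions and Y row counts differ")
  xs <- fit_scaler(P, "zscore")
  model <- if (stacker == "linear") {
    wiener_fit(P, Y)
  } else {
    if (!is.null(seed)) set.seed(seed)
    train_net("feedforward", apply_scaler(xs, P), Y, units = units,
              dropout = 0, epochs = epochs, lr = lr,
              batch_size = min(128, nrow(P)))
  }
  structure(list(stacker = stacker, model = model, xscaler = xs,
                 base_names = base_names, p = ncol(P), d = ncol(Y)),
            class = "ensemble_model")
}

#' @rdname ensemble_fit
#' @param object A fitted `ensemble_model`.
#' @param newdata K x (m*d) matrix (or named list) of base predictions.
#' @param ... Unused.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.matrix(newdata)) newdata <- do.call(cbind, newdata)
  P <- as.matrix(newdata)
  if (ncol(P) != object$p) stop_invalid_input("base prediction column count mismatch")
  if (object$stacker == "linear") predict(object$model, P)
  else predict(object$model, apply_scaler(object$xscaler, P))
}

#' @rdname ensemble_fit
#' @export
ensemble_predict <- function(object, newdata) predict(object, newdata)

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %s stacker over %d base column(s)\n", x$stacker, x$p))
  invisible(x)
}
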