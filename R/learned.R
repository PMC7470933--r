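#' Registry of decoder families
#'
#' Lists every decoder family the package provides, its input layout
#' (`flat` = K x (N*B) design matrix, `sequence` = K x N x B tensor,
#' `state_space` = decoder-specific), and its default hyperparameters.
#'
#' @return A tibble with columns `family`, `layout`, `defaults` (list).
#' @export
decoder_families <- function() {
  tibble::tibble(
    family = c("wiener", "wiener_cascade", "svr", "boosted_trees",
               "feedforward", "rnn", "gru", "lstm",
               "kalman", "naive_bayes", "ensemble"),
    layout = c("flat", "flat", "flat", "flat",
               "flat", "sequence", "sequence", "sequence",
               "state_space", "state_space", "meta"),
    defaults = list(
      list(ridge = 0),
      list(degree = 3, ridge = 0),
      list(cost = 10, epsilon = 0.1, max_train = Inf),
      list(max_depth = 4, nrounds = 300, eta = 0.1),
      list(units = 200, dropout = 0.2, epochs = 10, lr = 1e-2, batch_size = 128),
      list(units = 64, dropout = 0.2, epochs = 10, lr = 1e-2, batch_size = 128),
      list(units = 64, dropout = 0.2, epochs = 10, lr = 1e-2, batch_size = 128),
      list(units = 64, dropout = 0.2, epochs = 10, lr = 1e-2, batch_size = 128),
      list(noise_scale = 1, lag = 0),
      list(grid_resolution = NA, smoothing_bandwidth = 1, use_transition_prior = TRUE),
      list(stacker = "feedforward")))
}

#' Specify a decoder
#'
#' Builds a decoder specification: a family name plus hyperparameters
#' (unspecified ones filled from the registry defaults), the uniform entry
#' point to all eleven decoding methods.
#'
#' @param family One of the families in [decoder_families].
#' @param ... Named hyperparameter overrides.
#' @param seed Optional integer seed applied before stochastic fits.
#' @return Object of class `decoder_spec`.
#' @examples
#' decoder("lstm", units = 32, epochs = 5)
#' @export
decoder <- function(family, ..., seed = NULL) {
  reg <- decoder_families()
  if (!family %in% reg$family)
    stop_invalid_arg(sprintf("unknown decoder family '%s'", family))
  defaults <- reg$defaults[[match(family, reg$family)]]
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_invalid_arg(sprintf("unknown hyperparameter(s) for %s: %s",
                             family, paste(unknown, collapse = ", ")))
  hyper <- utils::modifyList(defaults, over)
  structure(list(family = family,
                 layout = reg$layout[[match(family, reg$family)]],
                 hyper = hyper, seed = seed),
            class = "decoder_spec")
}

#' @export
print.decoder_spec <- function(x, ...) {
  hp <- paste(names(x$hyper), unlist(lapply(x$hyper, format)), sep = "=", collapse = ", ")
  cat(sprintf("<decoder_spec> %s (%s layout): %s\n", x$family, x$layout, hp))
  invisible(x)
}

#' Fit a learned decoder under the uniform contract
#'
#' Fits one of the six learned families. Flat families (`svr`,
#' `boosted_trees`, `feedforward`) take the K x (N*B) design matrix;
#' recurrent families (`rnn`, `gru`, `lstm`) take the K x N x B sequence
#' tensor and predict from the hidden state after the final bin. All are
#' trained to minimise mean squared error. `svr` and `boosted_trees`
#' decode multiple outputs as independent per-dimension fits; the networks
#' fit all outputs jointly. SVR targets are z-scored internally and
#' predictions returned in original units.
#'
#' @param spec A [decoder] specification for a learned family.
#' @param X Feature matrix (flat families) or 3-D array (recurrent), or a
#'   `design_matrix`/`sequence_tensor` object.
#' @param Y Output matrix K x d (taken from `X` when it is a container).
#' @return Object of class `learned_decoder`.
#' @export
fit_learned <- function(spec, X, Y = NULL) {
  stopifnot(inherits(spec, "decoder_spec"))
  if (inherits(X, "design_matrix")) { Y <- Y %||% X$Y; X <- X$X }
  if (inherits(X, "sequence_tensor")) { Y <- Y %||% X$Y; X <- X$X3 }
  Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) stop_invalid_input("non-finite values in training data")
  is_seq <- length(dim(X)) == 3
  if (spec$layout == "sequence" && !is_seq)
    stop_invalid_arg(sprintf("family '%s' requires a K x N x B sequence tensor", spec$family))
  if (spec$layout == "flat" && is_seq)
    stop_invalid_arg(sprintf("family '%s' requires a flat K x (N*B) matrix", spec$family))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$hyper
  fit <- switch(spec$family,
    svr = {
      # kernel SVR cost grows quadratically with rows; `max_train` caps the
      # training set with an evenly spaced subsample when finite
      rows <- seq_len(nrow(X))
      if (is.finite(h$max_train) && h$max_train < nrow(X))
        rows <- round(seq(1, nrow(X), length.out = h$max_train))
      models <- lapply(seq_len(ncol(Y)), function(j) {
        ys <- fit_scaler(Y[rows, j, drop = FALSE], "zscore")
        yz <- drop(apply_scaler(ys, Y[rows, j, drop = FALSE]))
        list(svm = e1071::svm(x = X[rows, , drop = FALSE], y = yz,
                              type = "eps-regression", kernel = "radial",
                              cost = h$cost, epsilon = h$epsilon, scale = FALSE),
             yscaler = ys)
      })
      list(models = models)
    },
    boosted_trees = {
      models <- lapply(seq_len(ncol(Y)), function(j)
        xgboost::xgboost(X, Y[, j], nrounds = h$nrounds,
                         max_depth = h$max_depth, learning_rate = h$eta,
                         objective = "reg:squarederror", verbosity = 0,
                         nthreads = 1))
      list(models = models)
    },
    feedforward = ,
    rnn = ,
    gru = ,
    lstm = list(net = train_net(spec$family, X, Y, units = h$units,
                                dropout = h$dropout, epochs = h$epochs,
                                lr = h$lr, batch_size = h$batch_size)),
    stop_invalid_arg(sprintf("'%s' is not a learned family; use its dedicated fit function",
                             spec$family)))
  structure(c(fit, list(spec = spec, d = ncol(Y))), class = "learned_decoder")
}

#' Predict from a fitted learned decoder
#' @param object A `learned_decoder`.
#' @param newdata Matrix or tensor in the layout the family requires.
#' @param ... Unused.
#' @return K x d prediction matrix.
#' @export
predict.learned_decoder <- function(object, newdata, ...) {
  if (inherits(newdata, "design_matrix")) newdata <- newdata$X
  if (inherits(newdata, "sequence_tensor")) newdata <- newdata$X3
  fam <- object$spec$family
  K <- if (length(dim(newdata)) == 3) dim(newdata)[1] else nrow(newdata)
  out <- switch(fam,
    svr = vapply(object$models, function(m) {
      drop(invert_scaler(m$yscaler, matrix(predict(m$svm, newdata))))
    }, numeric(K)),
    boosted_trees = vapply(object$models, function(m)
      predict(m, newdata), numeric(K)),
    predict(object$net, newdata))
  matrix(out, nrow = K, ncol = object$d)
}

#' @rdname fit_learned
#' @param decoder A fitted `learned_decoder`.
#' @param newdata New features in the family's layout.
#' @export
predict_learned <- function(decoder, newdata) predict(decoder, newdata)

#' @export
print.learned_decoder <- function(x, ...) {
  cat(sprintf("<learned_decoder> %s, %d output(s)\n", x$spec$family, x$d))
  invisible(x)
}

#' Hyperparameter-robustness sweep for the feedforward decoder
#'
#' Fits the two-hidden-layer feedforward decoder over a grid of hidden-unit
#' counts and dropout proportions while holding the number of training
#' epochs constant, and scores each fit on a fixed held-out test split.
#' Mirrors the classic units-by-dropout sensitivity surface.
#'
#' @param X_train,Y_train Training design matrix and outputs (already
#'   preprocessed as desired).
#' @param X_test,Y_test Held-out rows scored with [r2_score].
#' @param units Vector of hidden-unit counts (both layers share the width).
#' @param dropouts Vector of dropout proportions in `[0, 1)`.
#' @param epochs Fixed number of training epochs (default 10).
#' @param seed Integer seed reused for every fit.
#' @param ... Further hyperparameters passed to the feedforward decoder.
#' @return A tibble of class `sweep_surface` with columns `units`,
#'   `dropout`, `r2`.
#' @export
sweep_feedforward <- function(X_train, Y_train, X_test, Y_test,
                              units = c(100, 300, 500), dropouts = c(0, 0.2, 0.4),
                              epochs = 10, seed = 1L, ...) {
  if (length(units) < 1 || length(dropouts) < 1)
    stop_invalid_arg("`units` and `dropouts` must be non-empty")
  grid <- expand.grid(units = units, dropout = dropouts)
  r2 <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- decoder("feedforward", units = grid$units[i], dropout = grid$dropout[i],
                    epochs = epochs, ..., seed = seed)
    fit <- fit_learned(spec, X_train, Y_train)
    r2_score(Y_test, predict(fit, X_test))
  }, numeric(1))
  out <- tibble::tibble(units = grid$units, dropout = grid$dropout, r2 = r2)
  class(out) <- c("sweep_surface", class(out))
  out
}
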