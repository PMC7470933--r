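#' Fraction-of-variance R-squared
#'
#' Computes, per output dimension, `1 - SS_res / SS_tot` with the mean
#' taken from the true outputs, then averages across dimensions (for 2-D
#' kinematics, the mean of the x- and y-component scores). This is the
#' fraction of variance accounted for — not a squared correlation — and can
#' be negative on held-out data when a decoder does worse than predicting
#' the mean.
#'
#' @param Y_true K x d matrix (or vector) of true outputs.
#' @param Y_hat K x d matrix (or vector) of predictions.
#' @return Scalar R-squared.
#' @examples
#' r2_score(c(0, 1, 2), c(0, 0, 0))  # -1.5
#' @export
r2_score <- function(Y_true, Y_hat) {
  Y_true <- as.matrix(Y_true); Y_hat <- as.matrix(Y_hat)
  if (!all(dim(Y_true) == dim(Y_hat))) stop_invalid_input("Y_true and Y_hat dimensions differ")
  if (nrow(Y_true) < 2) stop_invalid_input("need at least 2 rows")
  ss_tot <- colSums(sweep(Y_true, 2, colMeans(Y_true), "-")^2)
  if (any(ss_tot == 0))
    abort("true output has zero variance; R-squared undefined",
          class = "spikedecode_undefined_score")
  ss_res <- colSums((Y_hat - Y_true)^2)
  mean(1 - ss_res / ss_tot)
}

#' Contiguous-block cross-validation plan
#'
#' Splits K time-ordered rows into J folds. Each fold holds out one
#' contiguous test block (the J test blocks tile the recording exactly
#' once, rotating from the end of the recording backwards), an adjacent
#' contiguous validation block, and uses the remaining rows for training.
#' With J = 10 this gives the 80/10/10 train/validation/test split; when
#' J is too small for a 10% validation block (e.g. J = 2), the validation
#' block grows to half the non-test rows (50/25/25) with a warning.
#'
#' @param K Number of rows (time bins) to split.
#' @param J Number of folds (default 10).
#' @return Object of class `fold_plan`: list of folds, each with integer
#'   index vectors `train`, `validation`, `test`.
#' @export
make_fold_plan <- function(K, J = 10) {
  if (J < 2) stop_invalid_arg("`J` must be >= 2")
  if (K < 10 * J) stop_invalid_arg("K too small for J contiguous folds")
  bounds <- round(seq(0, K, length.out = J + 1))
  val_target <- round(K / 10)
  folds <- vector("list", J)
  warned <- FALSE
  for (f in seq_len(J)) {
    blk <- J - f + 1L                               # rotate from the end back
    test <- (bounds[blk] + 1L):bounds[blk + 1L]
    if (J < 4) {
      # test blocks over a quarter of the data: an 80/10/10-style split is
      # impossible, so the remainder splits evenly (50/25/25 at J = 2)
      val_size <- floor((K - length(test)) / 2)
      if (!warned) {
        warn(sprintf("80/10/10 split impossible with J = %d; using %d/%d/%d rows train/validation/test",
                     J, K - length(test) - val_size, val_size, length(test)))
        warned <- TRUE
      }
    } else {
      val_size <- min(val_target, floor((K - length(test)) / 2))
    }
    # contiguous validation block adjacent to the test block (before it,
    # unless the test block sits at the start of the recording)
    val <- if (bounds[blk] - val_size >= 0)
      (bounds[blk] - val_size + 1L):bounds[blk]
    else
      (bounds[blk + 1L] + 1L):(bounds[blk + 1L] + val_size)
    train <- setdiff(seq_len(K), c(test, val))
    folds[[f]] <- list(train = sort(train), validation = sort(val), test = test)
  }
  structure(list(folds = folds, K = as.integer(K), J = as.integer(J)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  f1 <- x$folds[[1]]
  cat(sprintf("<fold_plan> J = %d over K = %d rows (fold sizes %d/%d/%d train/val/test)\n",
              x$J, x$K, length(f1$train), length(f1$validation), length(f1$test)))
  invisible(x)
}

#' Fold-correlation-corrected standard error of the mean
#'
#' Across J cross-validation folds the training sets overlap, so fold
#' scores are positively correlated and the naive `sd/sqrt(J)` standard
#' error is too small. The corrected standard error is
#' `sd * sqrt(1/J + 1/(J-1))`.
#'
#' @param fold_scores Numeric vector of per-fold scores (length J >= 2).
#' @return Scalar corrected SEM.
#' @examples
#' corrected_sem(rnorm(10))
#' @export
corrected_sem <- function(fold_scores) {
  J <- length(fold_scores)
  if (J < 2) stop_invalid_arg("need at least 2 fold scores")
  sd(fold_scores) * sqrt(1 / J + 1 / (J - 1))
}

#' Block-bootstrap confidence interval for R-squared
#'
#' Temporally adjacent samples are highly correlated, so resampling
#' individual rows would produce unrealistically tight intervals. Instead
#' the test rows are cut into `n_subsets` contiguous, disjoint segments
#' covering the test set; each bootstrap resample draws `n_subsets`
#' segments with replacement, concatenates their (true, predicted) pairs,
#' and recomputes [r2_score]. The interval is the percentile interval of
#' the resampled scores.
#'
#' @param Y_true,Y_hat Test-set true outputs and predictions (K x d).
#' @param n_subsets Number of contiguous segments (default 20).
#' @param n_resamples Number of bootstrap draws (default 1000).
#' @param level Interval coverage (default 0.95; 0.68 approximates an SEM).
#' @param seed Optional integer seed for reproducible draws.
#' @return Named numeric `c(lower, upper)`; the resampled scores are
#'   attached as attribute `"resamples"`.
#' @export
block_bootstrap_ci <- function(Y_true, Y_hat, n_subsets = 20, n_resamples = 1000,
                               level = 0.95, seed = NULL) {
  Y_true <- as.matrix(Y_true); Y_hat <- as.matrix(Y_hat)
  K <- nrow(Y_true)
  if (K < n_subsets) stop_invalid_arg("fewer test rows than subsets")
  if (!is.null(seed)) set.seed(seed)
  bounds <- round(seq(0, K, length.out = n_subsets + 1))
  segs <- lapply(seq_len(n_subsets), function(i) (bounds[i] + 1L):bounds[i + 1L])
  r2s <- vapply(seq_len(n_resamples), function(b) {
    idx <- unlist(segs[sample.int(n_subsets, n_subsets, replace = TRUE)])
    r2_score(Y_true[idx, , drop = FALSE], Y_hat[idx, , drop = FALSE])
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- stats::quantile(r2s, c(a, 1 - a), names = FALSE)
  structure(c(lower = ci[1], upper = ci[2]), resamples = r2s, level = level)
}

base_family_names <- function()
  c("wiener", "wiener_cascade", "svr", "boosted_trees",
    "feedforward", "rnn", "gru", "lstm")

default_search_spaces <- function() {
  list(
    wiener = list(ridge = c(0, 100)),
    wiener_cascade = list(degree = list(lower = 1, upper = 5, integer = TRUE)),
    svr = list(cost = c(1, 1e4)),
    boosted_trees = list(max_depth = list(lower = 2, upper = 8, integer = TRUE),
                         nrounds = list(lower = 100, upper = 1000, integer = TRUE),
                         eta = c(0.01, 0.3)),
    feedforward = list(units = list(lower = 50, upper = 1000, integer = TRUE),
                       dropout = c(0, 0.5),
                       epochs = list(lower = 2, upper = 20, integer = TRUE)),
    rnn = list(units = list(lower = 50, upper = 400, integer = TRUE),
               dropout = c(0, 0.5),
               epochs = list(lower = 2, upper = 20, integer = TRUE)),
    gru = list(units = list(lower = 50, upper = 400, integer = TRUE),
               dropout = c(0, 0.5),
               epochs = list(lower = 2, upper = 20, integer = TRUE)),
    lstm = list(units = list(lower = 50, upper = 400, integer = TRUE),
                dropout = c(0, 0.5),
                epochs = list(lower = 2, upper = 20, integer = TRUE)),
    kalman = list(noise_scale = c(0.2, 20)),
    naive_bayes = list(smoothing_bandwidth = c(0.5, 3)))
}

fit_base_family <- function(family, hyper, Xtr, Ytr, seed) {
  set.seed(seed)
  switch(family,
    wiener = wiener_fit(Xtr, Ytr, ridge = hyper$ridge %||% 0),
    wiener_cascade = cascade_fit(Xtr, Ytr, degree = hyper$degree %||% 3,
                                 ridge = hyper$ridge %||% 0),
    fit_learned(do.call(decoder, c(list(family = family), hyper)), Xtr, Ytr))
}

# contiguous-run-aware kinematic states: derivatives never cross rows that
# are absent from `rows`, so no information flows in from held-out bins
kinematics_for_rows <- function(outputs, rows, bin_size, kind) {
  runs <- split(rows, cumsum(c(1, diff(rows) != 1)))
  out <- lapply(runs, function(r)
    kinematic_states(outputs[r, , drop = FALSE], bin_size, kind))
  do.call(rbind, out)
}

#' Compare decoders under nested contiguous cross-validation
#'
#' The full evaluation pipeline: for each fold of a J-fold contiguous
#' 80/10/10 plan, fits every requested decoder on the training rows
#' (optionally choosing hyperparameters by validation-set R-squared), and
#' scores the winning configuration on the test rows. Preprocessing
#' statistics (input z-scoring, output centring) are computed on training
#' rows only and reused on validation/test rows. The `"ensemble"`
#' pseudo-family stacks the other flat/sequence decoders in the run: its
#' stacker is trained on the bases' validation-set predictions — rows the
#' bases never trained on — and evaluated on their test-set predictions.
#'
#' @param data A [binned_dataset].
#' @param decoders Character vector of families (see [decoder_families]);
#'   may include `"ensemble"`.
#' @param lags Default [lag_spec] shared by the flat/sequence decoders.
#' @param lags_overrides Named list of per-family [lag_spec] overrides
#'   (commonly for `kalman` and `naive_bayes`).
#' @param folds Number of cross-validation folds J (default 10).
#' @param budget Hyperparameter evaluations per decoder per fold; 1 fits
#'   registry defaults without a search.
#' @param strategy Search strategy when `budget > 1`.
#' @param search_spaces Named list of per-family search spaces (defaults
#'   from the package's standard ranges).
#' @param hyper_overrides Named list of per-family fixed hyperparameter
#'   overrides applied outside (or underneath) any search, e.g.
#'   `list(svr = list(max_train = 2000))`.
#' @param output_kind `"velocity"` or `"position"`: what the dataset's
#'   output columns contain (determines the Kalman state layout and which
#'   state components are scored).
#' @param stacker Ensemble stacker, `"feedforward"` or `"linear"`.
#' @param use_transition_prior Naive Bayes sequential transition prior.
#' @param seed Integer master seed; all fold/decoder randomness derives
#'   from it.
#' @param verbose Print per-fold progress.
#' @return A tibble of class `decoder_comparison` with one row per decoder
#'   x fold (`decoder`, `fold`, `r2`, `hyper` list-column). Attributes:
#'   `predictions` (per decoder, per fold: test bins, truth, predictions),
#'   `audit` (per fold: row indices and preprocessing statistics), `plan`.
#' @export
run_comparison <- function(data, decoders, lags = lag_spec(5, 1, 0),
                           lags_overrides = list(), folds = 10, budget = 1,
                           strategy = c("bayesian", "random", "grid"),
                           search_spaces = list(), hyper_overrides = list(),
                           output_kind = c("velocity", "position"),
                           stacker = c("feedforward", "linear"),
                           use_transition_prior = TRUE,
                           seed = 1L, verbose = FALSE) {
  strategy <- match.arg(strategy)
  output_kind <- match.arg(output_kind)
  stacker <- match.arg(stacker)
  stopifnot(inherits(data, "binned_dataset"))
  known <- decoder_families()$family
  if (length(bad <- setdiff(decoders, known)))
    stop_invalid_arg(sprintf("unknown decoder(s): %s", paste(bad, collapse = ", ")))
  bases <- intersect(decoders, base_family_names())
  want_ens <- "ensemble" %in% decoders
  if (want_ens && length(bases) < 2)
    stop_invalid_arg("the ensemble needs at least two base decoders in `decoders`")
  spaces <- utils::modifyList(default_search_spaces(), search_spaces)

  dm <- make_design_matrix(data, lags)
  need_seq <- length(intersect(bases, c("rnn", "gru", "lstm"))) > 0
  dims3 <- c(nrow(dm$X), dm$n_neurons, lags$B)
  plan <- make_fold_plan(nrow(dm$X), folds)
  Y <- dm$Y
  d <- ncol(Y)

  nb_lags <- lags_overrides[["naive_bayes"]] %||% lags
  kal_lag_bins <- 0L
  wc <- if ("naive_bayes" %in% decoders) window_counts(data, nb_lags) else NULL

  results <- list(); preds <- list(); audit <- list()
  fam_seed <- function(f, family) (seed + 7919L * f + 131L * match(family, known)) %% .Machine$integer.max

  for (f in seq_len(folds)) {
    fold <- plan$folds[[f]]
    tr <- fold$train; va <- fold$validation; te <- fold$test
    xsc <- fit_scaler(dm$X[tr, , drop = FALSE], "zscore")
    ysc <- fit_scaler(Y[tr, , drop = FALSE], "center")
    Xtr <- apply_scaler(xsc, dm$X[tr, , drop = FALSE])
    Xva <- apply_scaler(xsc, dm$X[va, , drop = FALSE])
    Xte <- apply_scaler(xsc, dm$X[te, , drop = FALSE])
    Ytr <- apply_scaler(ysc, Y[tr, , drop = FALSE])
    Yva <- apply_scaler(ysc, Y[va, , drop = FALSE])
    to_seq <- function(X) array(X, c(nrow(X), dims3[2], dims3[3]))
    audit[[f]] <- list(train = tr, validation = va, test = te,
                       scaler_center = xsc$center, scaler_scale = xsc$scale,
                       y_center = ysc$center, hyper_logs = list(),
                       stacker_rows = if (want_ens) va else NULL)

    val_pred <- list(); test_pred <- list()
    for (family in bases) {
      seq_fam <- family %in% c("rnn", "gru", "lstm")
      ftr <- if (seq_fam) to_seq(Xtr) else Xtr
      fva <- if (seq_fam) to_seq(Xva) else Xva
      fte <- if (seq_fam) to_seq(Xte) else Xte
      hyper <- hyper_overrides[[family]] %||% list()
      if (budget > 1 && !is.null(spaces[[family]])) {
        opt <- optimize_hyperparameters(family, spaces[[family]], ftr, Ytr,
                                        fva, Yva, budget = budget,
                                        strategy = strategy,
                                        seed = fam_seed(f, family))
        hyper <- utils::modifyList(hyper, opt$best)
        audit[[f]]$hyper_logs[[family]] <- opt$log
      }
      fit <- fit_base_family(family, hyper, ftr, Ytr, fam_seed(f, family))
      pv <- invert_scaler(ysc, predict(fit, fva))
      pt <- invert_scaler(ysc, predict(fit, fte))
      val_pred[[family]] <- pv; test_pred[[family]] <- pt
      results[[length(results) + 1]] <- tibble::tibble(
        decoder = family, fold = f, r2 = r2_score(Y[te, , drop = FALSE], pt),
        hyper = list(hyper))
      preds[[family]][[f]] <- list(bins = dm$row_to_bin[te],
                                   truth = Y[te, , drop = FALSE], pred = pt)
      if (verbose) message(sprintf("fold %d %s R2 = %.3f", f, family,
                                   results[[length(results)]]$r2))
    }

    if (want_ens) {
      set.seed(fam_seed(f, "ensemble"))
      ens <- ensemble_fit(val_pred, Y[va, , drop = FALSE], stacker = stacker,
                          seed = fam_seed(f, "ensemble"))
      pt <- predict(ens, test_pred)
      results[[length(results) + 1]] <- tibble::tibble(
        decoder = "ensemble", fold = f,
        r2 = r2_score(Y[te, , drop = FALSE], pt), hyper = list(list(stacker = stacker)))
      preds[["ensemble"]][[f]] <- list(bins = dm$row_to_bin[te],
                                       truth = Y[te, , drop = FALSE], pred = pt)
    }

    if ("kalman" %in% decoders) {
      bins_tr <- dm$row_to_bin[tr]; bins_te <- dm$row_to_bin[te]
      zsc <- fit_scaler(data$counts[bins_tr, , drop = FALSE], "zscore")
      states_tr <- kinematics_for_rows(data$outputs, bins_tr, data$bin_size, output_kind)
      hyper <- list(noise_scale = 1)
      if (budget > 1) {
        bins_va <- dm$row_to_bin[va]
        km0 <- kalman_fit(states_tr, apply_scaler(zsc, data$counts[bins_tr, , drop = FALSE]),
                          lag = kal_lag_bins)
        obj <- function(p) {
          dec <- kalman_decode(km0, apply_scaler(zsc, data$counts[bins_va, , drop = FALSE]),
                               noise_scale = p$noise_scale)
          r2_score(data$outputs[bins_va, , drop = FALSE],
                   kalman_output_cols(dec, d, output_kind))
        }
        opt <- search_optimize(obj, spaces$kalman, budget, strategy,
                               seed = fam_seed(f, "kalman"))
        hyper <- opt$best
        audit[[f]]$hyper_logs[["kalman"]] <- opt$log
      }
      km <- kalman_fit(states_tr, apply_scaler(zsc, data$counts[bins_tr, , drop = FALSE]),
                       lag = kal_lag_bins, noise_scale = hyper$noise_scale)
      dec <- kalman_decode(km, apply_scaler(zsc, data$counts[bins_te, , drop = FALSE]))
      pt <- kalman_output_cols(dec, d, output_kind)
      results[[length(results) + 1]] <- tibble::tibble(
        decoder = "kalman", fold = f,
        r2 = r2_score(data$outputs[bins_te, , drop = FALSE], pt), hyper = list(hyper))
      preds[["kalman"]][[f]] <- list(bins = bins_te,
                                     truth = data$outputs[bins_te, , drop = FALSE], pred = pt)
    }

    if ("naive_bayes" %in% decoders) {
      rtb <- wc$row_to_bin
      wtr <- which(rtb %in% dm$row_to_bin[tr])
      wva <- which(rtb %in% dm$row_to_bin[va])
      wte <- which(rtb %in% dm$row_to_bin[te])
      hyper <- list(smoothing_bandwidth = 1)
      if (budget > 1) {
        obj <- function(p) {
          nbm <- nb_fit(wc$Y[wtr, , drop = FALSE], wc$counts[wtr, , drop = FALSE],
                        smoothing_bandwidth = p$smoothing_bandwidth)
          r2_score(wc$Y[wva, , drop = FALSE],
                   nb_decode(nbm, wc$counts[wva, , drop = FALSE],
                             use_transition_prior = use_transition_prior))
        }
        opt <- search_optimize(obj, spaces$naive_bayes, budget, strategy,
                               seed = fam_seed(f, "naive_bayes"))
        hyper <- opt$best
        audit[[f]]$hyper_logs[["naive_bayes"]] <- opt$log
      }
      nbm <- nb_fit(wc$Y[wtr, , drop = FALSE], wc$counts[wtr, , drop = FALSE],
                    smoothing_bandwidth = hyper$smoothing_bandwidth)
      pt <- nb_decode(nbm, wc$counts[wte, , drop = FALSE],
                      use_transition_prior = use_transition_prior)
      results[[length(results) + 1]] <- tibble::tibble(
        decoder = "naive_bayes", fold = f,
        r2 = r2_score(wc$Y[wte, , drop = FALSE], pt), hyper = list(hyper))
      preds[["naive_bayes"]][[f]] <- list(bins = rtb[wte],
                                          truth = wc$Y[wte, , drop = FALSE], pred = pt)
    }
    if (verbose) message(sprintf("fold %d/%d done", f, folds))
  }

  out <- dplyr::bind_rows(results)
  class(out) <- c("decoder_comparison", class(out))
  attr(out, "predictions") <- preds
  attr(out, "audit") <- audit
  attr(out, "plan") <- plan
  attr(out, "seed") <- seed
  out
}

kalman_output_cols <- function(states, d, output_kind) {
  cols <- if (output_kind == "position") seq_len(d) else d + seq_len(d)
  states[, cols, drop = FALSE]
}

#' @export
tidy.decoder_comparison <- function(x, ...) {
  tibble::as_tibble(x[, c("decoder", "fold", "r2")])
}

#' @export
glance.decoder_comparison <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$decoder) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), sd_r2 = sd(.data$r2),
                     sem = corrected_sem(.data$r2), n_folds = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_r2))
}

#' @export
print.decoder_comparison <- function(x, ...) {
  cat("<decoder_comparison> mean test R2 (corrected SEM) across folds:\n")
  print(as.data.frame(glance.decoder_comparison(x)), row.names = FALSE)
  invisible(x)
}
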