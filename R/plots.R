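#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar geom_tile
#'   geom_line labs scale_fill_viridis_c theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a decoder comparison as mean R-squared with corrected-SEM bars
#'
#' One point per decoder (mean test R-squared across folds) with error bars
#' of one corrected SEM, plus the individual fold scores as small crosses.
#'
#' @param object A `decoder_comparison` from [run_comparison].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoder_comparison <- function(object, ...) {
  gl <- glance(object)
  gl$decoder <- factor(gl$decoder, levels = gl$decoder)
  td <- tidy(object)
  td$decoder <- factor(td$decoder, levels = levels(gl$decoder))
  ggplot(gl, aes(x = .data$decoder, y = .data$mean_r2)) +
    geom_errorbar(aes(ymin = .data$mean_r2 - .data$sem,
                      ymax = .data$mean_r2 + .data$sem), width = 0.25) +
    geom_point(size = 3) +
    geom_point(data = td, aes(y = .data$r2), shape = 4, alpha = 0.5) +
    labs(x = NULL, y = expression(test~R^2),
         title = "Decoder comparison (mean ± corrected SEM across folds)") +
    theme_minimal()
}

#' Plot a feedforward hyperparameter sweep surface
#'
#' Tile map of test R-squared over hidden-unit count and dropout
#' proportion, colour range clipped to the top 0.2 of R-squared.
#'
#' @param object A `sweep_surface` from [sweep_feedforward].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_surface <- function(object, ...) {
  lims <- c(max(object$r2) - 0.2, max(object$r2))
  ggplot(object, aes(x = factor(.data$units), y = factor(.data$dropout),
                     fill = pmax(.data$r2, lims[1]))) +
    geom_tile() +
    scale_fill_viridis_c(name = expression(R^2), limits = lims) +
    labs(x = "hidden units per layer", y = "dropout proportion") +
    theme_minimal()
}

#' Plot decoded versus true output traces
#'
#' Overlays, for one decoder and fold, the decoded test-set trace on the
#' ground truth, one panel per output dimension.
#'
#' @param report A `decoder_comparison` (run with predictions retained,
#'   the default).
#' @param decoder Decoder family name present in the report.
#' @param fold Fold number (default 1).
#' @return A ggplot object.
#' @export
plot_predictions <- function(report, decoder, fold = 1) {
  preds <- attr(report, "predictions")
  if (is.null(preds[[decoder]]) || length(preds[[decoder]]) < fold)
    stop_invalid_arg("no stored predictions for that decoder/fold")
  p <- preds[[decoder]][[fold]]
  d <- ncol(p$truth)
  df <- tibble::tibble(
    bin = rep(p$bins, times = 2 * d),
    dim = rep(rep(colnames(p$truth) %||% paste0("out", seq_len(d)), each = length(p$bins)), 2),
    what = rep(c("true", "decoded"), each = length(p$bins) * d),
    value = c(as.vector(p$truth), as.vector(p$pred)))
  ggplot(df, aes(x = .data$bin, y = .data$value, colour = .data$what)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~dim, ncol = 1, scales = "free_y") +
    labs(x = "time bin", y = NULL, colour = NULL,
         title = sprintf("%s, fold %d", decoder, fold)) +
    theme_minimal()
}
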