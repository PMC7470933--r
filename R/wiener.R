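#' Wiener filter: lagged multiple linear regression
#'
#' Fits ordinary least squares from the flattened lag-window features to the
#' outputs, one weight per neuron-lag feature plus an intercept. This is the
#' classical linear decoder: the output is modelled as an affine function of
#' the spike counts in the B relevant bins of every neuron. An optional ridge
#' penalty is exposed as a hyperparameter (default 0, plain OLS).
#'
#' @param X Numeric matrix K x P of lagged features (or a `design_matrix`,
#'   whose `X`/`Y` are then used).
#' @param Y Numeric matrix K x d of outputs (ignored when `X` is a
#'   `design_matrix`).
#' @param ridge Non-negative L2 penalty on the non-intercept weights.
#' @return Object of class `wiener_filter` with `weights` ((P+1) x d,
#'   intercept first row).
#' @examples
#' X <- matrix(0:2, ncol = 1); Y <- matrix(c(0, 2, 4))
#' coef(wiener_fit(X, Y))   # intercept 0, slope 2
#' @export
wiener_fit <- function(X, Y = NULL, ridge = 0) {
  if (inherits(X, "design_matrix")) { Y <- X$Y; X <- X$X }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_invalid_input("X and Y row counts differ")
  if (anyNA(X) || anyNA(Y)) stop_invalid_input("missing values in X or Y")
  if (nrow(X) <= ncol(X)) warn("fewer rows than features; fit is interpolating")
  Xa <- cbind(`(Intercept)` = 1, X)
  if (ridge > 0) {
    P <- ncol(Xa)
    pen <- diag(ridge, P); pen[1, 1] <- 0   # intercept unpenalised
    W <- solve(crossprod(Xa) + pen, crossprod(Xa, Y))
  } else {
    qx <- qr(Xa)
    if (qx$rank < ncol(Xa)) {
      warn("rank-deficient features; using minimum-norm least squares")
      sv <- svd(Xa)
      pos <- sv$d > max(dim(Xa)) * .Machine$double.eps * sv$d[1]
      W <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], Y)) / sv$d[pos])
    } else {
      W <- qr.coef(qx, Y)
    }
  }
  dimnames(W) <- list(c("(Intercept)", colnames(X) %||% paste0("x", seq_len(ncol(X)))),
                      colnames(Y) %||% paste0("y", seq_len(ncol(Y))))
  structure(list(weights = W, ridge = ridge), class = "wiener_filter")
}

#' @export
coef.wiener_filter <- function(object, ...) object$weights

#' Predict from a fitted Wiener filter
#' @param object A `wiener_filter`.
#' @param newdata Feature matrix K x P (or `design_matrix`).
#' @param ... Unused.
#' @return Matrix K x d of predictions.
#' @export
predict.wiener_filter <- function(object, newdata, ...) {
  if (inherits(newdata, "design_matrix")) newdata <- newdata$X
  cbind(1, as.matrix(newdata)) %*% object$weights
}

#' @export
print.wiener_filter <- function(x, ...) {
  cat(sprintf("<wiener_filter> %d features -> %d output(s)%s\n",
              nrow(x$weights) - 1, ncol(x$weights),
              if (x$ridge > 0) sprintf(", ridge %g", x$ridge) else ""))
  invisible(x)
}

#' @export
tidy.wiener_filter <- function(x, ...) {
  W <- x$weights
  tibble::tibble(
    term = rep(rownames(W), ncol(W)),
    response = rep(colnames(W), each = nrow(W)),
    estimate = as.vector(W))
}

#' Wiener cascade: linear stage plus fitted static polynomial
#'
#' A linear-nonlinear decoder: per output dimension, a single-output Wiener
#' filter is fitted first, then a static polynomial of the given degree maps
#' the linear stage's training predictions onto the training outputs by
#' ordinary least squares. The nonlinearity is purely a function of the
#' linear output, so no nonlinear mixing of features occurs. Degree 1
#' reduces to an affine re-fit of the linear stage, leaving its predictions
#' unchanged.
#'
#' @inheritParams wiener_fit
#' @param degree Polynomial degree (>= 1), a hyperparameter usually chosen
#'   on a validation set.
#' @return Object of class `wiener_cascade` with per-dimension `linear`
#'   stages and `poly_coeffs` (each length degree+1, ascending powers).
#' @export
cascade_fit <- function(X, Y = NULL, degree = 3, ridge = 0) {
  if (inherits(X, "design_matrix")) { Y <- X$Y; X <- X$X }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (degree < 1 || degree != round(degree)) stop_invalid_arg("`degree` must be a positive integer")
  if (degree >= nrow(X)) stop_invalid_arg("`degree` must be smaller than the number of rows")
  d <- ncol(Y)
  linear <- vector("list", d); pc <- vector("list", d)
  for (j in seq_len(d)) {
    lf <- wiener_fit(X, Y[, j, drop = FALSE], ridge = ridge)
    z <- drop(predict(lf, X))
    V <- outer(z, 0:degree, `^`)
    cf <- qr.coef(qr(V), Y[, j])
    cf[is.na(cf)] <- 0    # collinear high powers (e.g. constant z)
    linear[[j]] <- lf; pc[[j]] <- cf
  }
  structure(list(linear = linear, poly_coeffs = pc, degree = as.integer(degree),
                 d = d), class = "wiener_cascade")
}

#' @rdname cascade_fit
#' @param object A `wiener_cascade`.
#' @param newdata Feature matrix (or `design_matrix`).
#' @param ... Unused.
#' @export
predict.wiener_cascade <- function(object, newdata, ...) {
  if (inherits(newdata, "design_matrix")) newdata <- newdata$X
  out <- vapply(seq_len(object$d), function(j) {
    z <- drop(predict(object$linear[[j]], newdata))
    drop(outer(z, 0:object$degree, `^`) %*% object$poly_coeffs[[j]])
  }, numeric(nrow(newdata)))
  matrix(out, nrow = nrow(newdata), ncol = object$d)
}

#' @export
print.wiener_cascade <- function(x, ...) {
  cat(sprintf("<wiener_cascade> degree %d, %d output(s)\n", x$degree, x$d))
  invisible(x)
}
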