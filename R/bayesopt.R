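# Search-strategy engine for hyperparameter optimization. The Bayesian
# strategy is a small Gaussian-process surrogate (squared-exponential
# kernel on the unit cube, standardized responses) with expected
# improvement maximised over a dense random candidate set.

parse_space <- function(search_space) {
  stopifnot(is.list(search_space), length(search_space) >= 1, !is.null(names(search_space)))
  lapply(search_space, function(e) {
    if (is.numeric(e) && length(e) == 2 && is.null(names(e)))
      return(list(lower = e[1], upper = e[2], integer = FALSE, values = NULL))
    if (is.list(e)) {
      if (!is.null(e$values)) return(list(lower = NA, upper = NA, integer = FALSE, values = e$values))
      return(list(lower = e$lower, upper = e$upper,
                  integer = isTRUE(e$integer), values = NULL))
    }
    if (is.numeric(e) && length(e) > 2)
      return(list(lower = NA, upper = NA, integer = FALSE, values = e))
    stop_invalid_arg("each search-space entry must be c(lower, upper), a value set, or a list")
  })
}

# map unit-cube coordinates to a named hyperparameter list
space_decode <- function(u, sp) {
  out <- vector("list", length(sp)); names(out) <- names(sp)
  for (k in seq_along(sp)) {
    e <- sp[[k]]
    if (!is.null(e$values)) {
      i <- 1 + floor(unname(u[k]) * length(e$values) * (1 - 1e-12))
      out[[k]] <- e$values[[i]]
    } else {
      v <- e$lower + unname(u[k]) * (e$upper - e$lower)
      out[[k]] <- if (e$integer) as.integer(round(v)) else v
    }
  }
  out
}

gp_ei_propose <- function(U, y, n_cand = 500, lengthscale = 0.2) {
  dims <- ncol(U)
  ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  yz <- (y - ym) / ys
  Kmat <- exp(-0.5 * as.matrix(stats::dist(U))^2 / lengthscale^2)
  diag(Kmat) <- diag(Kmat) + 1e-6
  Kc <- chol(Kmat)
  alpha <- backsolve(Kc, backsolve(Kc, yz, transpose = TRUE))
  cand <- matrix(runif(n_cand * dims), n_cand, dims)
  D2 <- outer(rowSums(cand^2), rowSums(U^2), "+") - 2 * cand %*% t(U)
  Kx <- exp(-0.5 * pmax(D2, 0) / lengthscale^2)
  mu <- drop(Kx %*% alpha)
  v <- backsolve(Kc, t(Kx), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- max(yz)
  z <- (mu - best) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  cand[which.max(ei), , drop = TRUE]
}

#' Search a hyperparameter space against an objective
#'
#' Engine behind [optimize_hyperparameters]: maximises `objective(params)`
#' over a bounded search space with a choice of strategy. `"grid"` samples
#' values evenly, `"random"` uses a Latin hypercube, and `"bayesian"` seeds
#' with a small Latin hypercube then proposes points by Gaussian-process
#' expected improvement.
#'
#' @param objective Function taking a named list of hyperparameters and
#'   returning a scalar to maximise (e.g. validation R-squared). Failed
#'   evaluations may return `NA`/`-Inf`.
#' @param search_space Named list; each entry is `c(lower, upper)`, a list
#'   with `lower`/`upper`/`integer = TRUE`, or `list(values = ...)` for a
#'   discrete set.
#' @param budget Number of objective evaluations (>= 1).
#' @param strategy `"bayesian"`, `"random"`, or `"grid"`.
#' @param seed Optional integer seed.
#' @return List with `best` (hyperparameter list), `best_value`, and `log`
#'   (tibble of every evaluation).
#' @export
search_optimize <- function(objective, search_space, budget,
                            strategy = c("bayesian", "random", "grid"),
                            seed = NULL) {
  strategy <- match.arg(strategy)
  if (budget < 1) stop_invalid_arg("`budget` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sp <- parse_space(search_space)
  dims <- length(sp)
  U <- switch(strategy,
    grid = {
      per <- max(1L, floor(budget^(1 / dims)))
      pts <- if (per == 1) 0.5 else seq(0, 1, length.out = per)
      g <- as.matrix(expand.grid(rep(list(pts), dims)))
      g[seq_len(min(nrow(g), budget)), , drop = FALSE]
    },
    random = lhs::randomLHS(budget, dims),
    bayesian = lhs::randomLHS(min(budget, max(3, dims + 2)), dims))
  evals <- list(); vals <- numeric(0)
  eval_point <- function(u) {
    params <- space_decode(u, sp)
    v <- tryCatch(objective(params), error = function(e) NA_real_)
    if (is.null(v) || !is.finite(v)) v <- -Inf
    evals[[length(evals) + 1]] <<- params
    vals <<- c(vals, v)
  }
  for (i in seq_len(nrow(U))) eval_point(U[i, ])
  if (strategy == "bayesian") {
    while (length(vals) < budget) {
      ok <- is.finite(vals)
      u_next <- if (sum(ok) >= 2)
        gp_ei_propose(U[ok, , drop = FALSE], vals[ok])
      else runif(dims)
      U <- rbind(U, u_next)
      eval_point(u_next)
    }
  }
  if (all(!is.finite(vals)))
    abort("all hyperparameter evaluations failed", class = "spikedecode_fit_failure")
  log <- tibble::as_tibble(do.call(rbind, lapply(evals, function(p)
    as.data.frame(lapply(p, function(x) if (is.numeric(x)) x else as.character(x))))))
  log$value <- vals
  best <- which.max(vals)
  list(best = evals[[best]], best_value = vals[best], log = log)
}

#' Optimise decoder hyperparameters on a validation set
#'
#' Fits the given decoder family on the training rows for many
#' hyperparameter settings and returns the configuration with the highest
#' validation-set R-squared. The test set plays no role here: selection
#' uses validation data only.
#'
#' @param family A learned or classical decoder family name (see
#'   [decoder_families]); state-space families `kalman`/`naive_bayes` are
#'   supported through their own fit/decode routines by the pipeline.
#' @param search_space See [search_optimize].
#' @param X_train,Y_train Training features (layout per family) and outputs.
#' @param X_val,Y_val Validation features and outputs.
#' @param budget Number of configurations to evaluate.
#' @param strategy Search strategy (default `"bayesian"`).
#' @param seed Optional seed.
#' @return As [search_optimize].
#' @export
optimize_hyperparameters <- function(family, search_space, X_train, Y_train,
                                     X_val, Y_val, budget = 10,
                                     strategy = c("bayesian", "random", "grid"),
                                     seed = NULL) {
  strategy <- match.arg(strategy)
  objective <- function(params) {
    spec <- do.call(decoder, c(list(family = family), params))
    fit <- switch(family,
      wiener = wiener_fit(X_train, Y_train, ridge = spec$hyper$ridge),
      wiener_cascade = cascade_fit(X_train, Y_train, degree = spec$hyper$degree,
                                   ridge = spec$hyper$ridge),
      fit_learned(spec, X_train, Y_train))
    r2_score(Y_val, predict(fit, X_val))
  }
  search_optimize(objective, search_space, budget, strategy, seed = seed)
}
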