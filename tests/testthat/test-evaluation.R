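test_that("r2_score reproduces hand-computed values including the negative case", {
  y <- matrix(rnorm(30), 15, 2)
  expect_equal(r2_score(y, y), 1)
  ybar <- matrix(colMeans(y), 15, 2, byrow = TRUE)
  expect_equal(r2_score(y, ybar), 0)
  expect_equal(r2_score(c(0, 1, 2), c(0, 0, 0)), -1.5)
})

test_that("r2_score equals a two-line oracle on random inputs", {
  set.seed(61)
  for (i in 1:20) {
    d <- sample(1:3, 1)
    y <- matrix(rnorm(40 * d), 40, d)
    p <- matrix(rnorm(40 * d), 40, d)
    oracle <- mean(1 - colSums((p - y)^2) /
                     colSums(sweep(y, 2, colMeans(y))^2))
    expect_equal(r2_score(y, p), oracle, tolerance = 1e-12)
  }
})

test_that("r2_score rejects degenerate inputs", {
  expect_error(r2_score(rep(1, 5), rnorm(5)), class = "spikedecode_undefined_score")
  expect_error(r2_score(rnorm(5), rnorm(4)), class = "spikedecode_invalid_input")
})

test_that("the 10-fold plan tiles K = 100 exactly as specified", {
  plan <- make_fold_plan(100, 10)
  expect_equal(plan$folds[[1]]$test, 91:100)
  expect_equal(plan$folds[[2]]$test, 81:90)
  expect_equal(plan$folds[[10]]$test, 1:10)
  all_tests <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(all_tests, 1:100)                       # tiles exactly once
  for (f in plan$folds) {
    expect_length(f$train, 80)
    expect_length(f$validation, 10)
    expect_length(f$test, 10)
    expect_equal(sort(c(f$train, f$validation, f$test)), 1:100)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_equal(f$validation, min(f$validation):max(f$validation)) # contiguous
    expect_equal(f$test, min(f$test):max(f$test))
  }
})

test_that("J = 2 falls back to a 50/25/25 split with a warning", {
  expect_warning(plan <- make_fold_plan(100, 2), "80/10/10")
  f <- plan$folds[[1]]
  expect_length(f$test, 50)
  expect_length(f$validation, 25)
  expect_length(f$train, 25)
  expect_error(make_fold_plan(15, 2), class = "spikedecode_invalid_argument")
})

test_that("corrected SEM follows sigma * sqrt(1/J + 1/(J-1))", {
  expect_equal(corrected_sem(rep(0.5, 8)), 0)
  x <- rnorm(10); x <- x / sd(x)                  # sigma exactly 1, J = 10
  expect_equal(corrected_sem(x), sqrt(1 / 10 + 1 / 9), tolerance = 1e-12)
  expect_equal(round(corrected_sem(x), 4), 0.4595)
  for (J in c(2, 5, 10, 20)) {
    y <- rnorm(J)
    expect_gt(corrected_sem(y) + 1e-15, sd(y) / sqrt(J))  # always above naive
  }
  expect_error(corrected_sem(1), class = "spikedecode_invalid_argument")
})

test_that("block bootstrap honours its defaults and is seeded", {
  set.seed(62)
  y <- matrix(rnorm(400), 200, 2)
  ci <- block_bootstrap_ci(y, y, seed = 1)
  expect_equal(as.numeric(ci), c(1, 1))
  expect_length(attr(ci, "resamples"), 1000)     # default 1000 resamples

  p <- y + rnorm(400, 0, 0.7)
  c1 <- block_bootstrap_ci(y, p, seed = 5)
  c2 <- block_bootstrap_ci(y, p, seed = 5)
  expect_identical(c1, c2)
  c3 <- block_bootstrap_ci(y, p, seed = 6)
  expect_false(identical(c1, c3))
  expect_lt(c1["lower"], c1["upper"])
  expect_error(block_bootstrap_ci(y[1:10, ], p[1:10, ]),
               class = "spikedecode_invalid_argument")
})

test_that("more, shorter segments narrow the interval on exchangeable data", {
  set.seed(63)
  y <- matrix(rnorm(4000)); p <- y + rnorm(4000, 0, 1)
  w <- function(ns) { ci <- block_bootstrap_ci(y, p, n_subsets = ns, seed = 2)
                      ci["upper"] - ci["lower"] }
  expect_lt(w(100), w(20))
})

test_that("search strategies return the evaluated maximum", {
  quad <- function(p) -(p$x - 0.3)^2
  for (strat in c("grid", "random", "bayesian")) {
    res <- search_optimize(quad, list(x = c(0, 1)), budget = 15,
                           strategy = strat, seed = 3)
    expect_equal(res$best_value, max(res$log$value))
    expect_equal(quad(res$best), res$best_value)
    expect_equal(nrow(res$log), if (strat == "grid") 15 else 15)
  }
  # Bayesian search localises a 1-D quadratic optimum within 10%
  res <- search_optimize(quad, list(x = c(0, 1)), budget = 15,
                         strategy = "bayesian", seed = 4)
  expect_lt(abs(res$best$x - 0.3), 0.1)
  # budget 1 returns the single evaluated point
  res1 <- search_optimize(quad, list(x = c(0, 1)), budget = 1,
                          strategy = "random", seed = 5)
  expect_equal(nrow(res1$log), 1L)
  expect_error(search_optimize(quad, list(x = c(0, 1)), budget = 0),
               class = "spikedecode_invalid_argument")
})

test_that("integer and discrete search dimensions decode correctly", {
  seen <- integer(0)
  obj <- function(p) { seen <<- c(seen, p$k); -abs(p$k - 3) + p$flag }
  res <- search_optimize(obj, list(k = list(lower = 1, upper = 5, integer = TRUE),
                                   flag = list(values = c(0, 10))),
                         budget = 12, strategy = "random", seed = 6)
  expect_true(all(seen == round(seen)))
  expect_true(res$best$flag %in% c(0, 10))
})

test_that("optimize_hyperparameters selects by validation score only", {
  lin <- make_linear_design(120, 3, d = 1, noise = 0.4, seed = 64)
  tr <- 1:80; va <- 81:120
  res <- optimize_hyperparameters("wiener", list(ridge = c(0, 50)),
                                  lin$X[tr, ], lin$Y[tr, , drop = FALSE],
                                  lin$X[va, ], lin$Y[va, , drop = FALSE],
                                  budget = 6, strategy = "random", seed = 7)
  # the returned config is the argmax of the logged validation scores
  expect_equal(res$best_value, max(res$log$value))
  refit <- wiener_fit(lin$X[tr, ], lin$Y[tr, , drop = FALSE], ridge = res$best$ridge)
  expect_equal(r2_score(lin$Y[va, , drop = FALSE], predict(refit, lin$X[va, ])),
               res$best_value, tolerance = 1e-10)
})

test_that("a two-fold single-decoder comparison equals the manual sequence", {
  sim <- simulate_cortical(n_neurons = 8, duration = 120, seed = 65)
  lg <- lag_spec(2, 1, 0)
  suppressWarnings(rep <- run_comparison(sim$binned, "wiener", lags = lg,
                                         folds = 2, seed = 66))
  dm <- make_design_matrix(sim$binned, lg)
  aud <- attr(rep, "audit")[[1]]
  xs <- fit_scaler(dm$X[aud$train, ], "zscore")
  ys <- fit_scaler(dm$Y[aud$train, ], "center")
  fit <- wiener_fit(apply_scaler(xs, dm$X[aud$train, ]),
                    apply_scaler(ys, dm$Y[aud$train, ]))
  manual <- r2_score(dm$Y[aud$test, ],
                     invert_scaler(ys, predict(fit, apply_scaler(xs, dm$X[aud$test, ]))))
  expect_equal(rep$r2[rep$fold == 1], manual, tolerance = 1e-10)
})

test_that("comparison reports serialise to JSON with fold-level detail", {
  sim <- simulate_cortical(n_neurons = 6, duration = 100, seed = 67)
  suppressWarnings(rep <- run_comparison(sim$binned, c("wiener", "wiener_cascade"),
                                         lags = lag_spec(1, 1, 0), folds = 2,
                                         seed = 68))
  path <- tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(back$summary$decoder, c("wiener", "wiener_cascade"))
  expect_equal(nrow(back$folds), 4L)
  expect_equal(back$folds$r2, rep$r2, tolerance = 1e-12)
  gl <- glance(rep)
  expect_named(gl, c("decoder", "mean_r2", "sd_r2", "sem", "n_folds"))
  expect_equal(gl$sem, vapply(gl$decoder, function(dd)
    corrected_sem(rep$r2[rep$decoder == dd]), numeric(1), USE.NAMES = FALSE))
})
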