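# finite-difference check of the analytic gradients for every network family
test_that("network gradients match central finite differences", {
  set.seed(41)
  K <- 6; N <- 3; B <- 4; d <- 2
  X3 <- array(rnorm(K * N * B), c(K, N, B))
  Xf <- matrix(rnorm(K * 8), K, 8)
  Y <- matrix(rnorm(K * d), K, d)
  eps <- 1e-6
  for (fam in c("feedforward", "rnn", "gru", "lstm")) {
    X <- if (fam == "feedforward") Xf else X3
    nin <- if (fam == "feedforward") 8 else N
    p <- spikedecode:::net_funs[[fam]]$init(nin, 5, d)
    lg <- spikedecode:::net_loss_grad(fam, p, X, Y, 0, train = FALSE)
    for (nm in names(p)) {
      idx <- cbind(sample(nrow(p[[nm]]), 2, replace = TRUE),
                   sample(ncol(p[[nm]]), 2, replace = TRUE))
      for (r in 1:2) {
        pp <- p; pp[[nm]][idx[r, 1], idx[r, 2]] <- p[[nm]][idx[r, 1], idx[r, 2]] + eps
        up <- spikedecode:::net_loss_grad(fam, pp, X, Y, 0, train = FALSE)$loss
        pp[[nm]][idx[r, 1], idx[r, 2]] <- p[[nm]][idx[r, 1], idx[r, 2]] - eps
        dn <- spikedecode:::net_loss_grad(fam, pp, X, Y, 0, train = FALSE)$loss
        num <- (up - dn) / (2 * eps)
        expect_equal(lg$grads[[nm]][idx[r, 1], idx[r, 2]], num, tolerance = 1e-5,
                     label = sprintf("%s grad %s", fam, nm))
      }
    }
  }
})

test_that("every learned family fits exactly linear noiseless data well", {
  lin <- make_linear_design(600, 6, d = 2, noise = 0, seed = 42)
  lin$X <- scale(lin$X)
  X3 <- array(lin$X, c(600, 3, 2))
  for (fam in c("svr", "boosted_trees", "feedforward")) {
    fit <- fit_learned(decoder(fam, seed = 1), lin$X, lin$Y)
    expect_gte(r2_score(lin$Y, predict(fit, lin$X)), 0.95)
  }
  for (fam in c("rnn", "gru", "lstm")) {
    fit <- fit_learned(decoder(fam, dropout = 0, epochs = 20, seed = 1), X3, lin$Y)
    expect_gte(r2_score(lin$Y, predict(fit, X3)), 0.95)
  }
})

test_that("svr and boosted trees decode multiple outputs independently", {
  lin <- make_linear_design(150, 4, d = 2, noise = 0.2, seed = 43)
  for (fam in c("svr", "boosted_trees")) {
    joint <- fit_learned(decoder(fam, seed = 1), lin$X, lin$Y)
    pj <- predict(joint, lin$X)
    for (j in 1:2) {
      single <- fit_learned(decoder(fam, seed = 1), lin$X, lin$Y[, j, drop = FALSE])
      expect_equal(pj[, j], drop(predict(single, lin$X)), tolerance = 1e-10)
    }
  }
})

test_that("seeded refits are reproducible", {
  lin <- make_linear_design(200, 5, d = 1, noise = 0.3, seed = 44)
  a <- predict(fit_learned(decoder("boosted_trees", seed = 7), lin$X, lin$Y), lin$X)
  b <- predict(fit_learned(decoder("boosted_trees", seed = 7), lin$X, lin$Y), lin$X)
  expect_identical(a, b)
  X3 <- array(lin$X, c(200, 5, 1))
  n1 <- predict(fit_learned(decoder("gru", seed = 7), X3, lin$Y), X3)
  n2 <- predict(fit_learned(decoder("gru", seed = 7), X3, lin$Y), X3)
  expect_identical(n1, n2)
  n3 <- predict(fit_learned(decoder("gru", seed = 8), X3, lin$Y), X3)
  expect_false(identical(n1, n3))
})

test_that("layout mismatches and bad hyperparameters are rejected", {
  lin <- make_linear_design(50, 4, seed = 45)
  X3 <- array(lin$X, c(50, 2, 2))
  expect_error(fit_learned(decoder("lstm"), lin$X, lin$Y),
               class = "spikedecode_invalid_argument")
  expect_error(fit_learned(decoder("svr"), X3, lin$Y),
               class = "spikedecode_invalid_argument")
  expect_error(decoder("nope"), class = "spikedecode_invalid_argument")
  expect_error(decoder("svr", bogus = 1), class = "spikedecode_invalid_argument")
  bad <- lin$X; bad[1, 1] <- NA
  expect_error(fit_learned(decoder("svr"), bad, lin$Y),
               class = "spikedecode_invalid_input")
})

test_that("a B = 1 recurrent decoder sees the same information as a flat net", {
  set.seed(46)
  sim <- simulate_cortical(n_neurons = 15, duration = 150, mean_rate = 5,
                           tuning_depth = 3, seed = 46)
  dm <- make_design_matrix(sim$binned, lag_spec(0, 1, 0))
  K <- nrow(dm$X); tr <- 1:floor(0.8 * K); te <- (floor(0.8 * K) + 1):K
  xs <- fit_scaler(dm$X[tr, ], "zscore")
  Xtr <- apply_scaler(xs, dm$X[tr, ]); Xte <- apply_scaler(xs, dm$X[te, ])
  mlp <- fit_learned(decoder("feedforward", seed = 1), Xtr, dm$Y[tr, ])
  rnn <- fit_learned(decoder("rnn", seed = 1),
                     array(Xtr, c(nrow(Xtr), 15, 1)), dm$Y[tr, ])
  r_m <- r2_score(dm$Y[te, ], predict(mlp, Xte))
  r_r <- r2_score(dm$Y[te, ], predict(rnn, array(Xte, c(nrow(Xte), 15, 1))))
  expect_lt(abs(r_m - r_r), 0.2)
})

test_that("the feedforward sweep holds epochs fixed and degenerates to one fit", {
  lin <- make_linear_design(300, 6, d = 1, noise = 0.5, seed = 47)
  tr <- 1:240; te <- 241:300
  surf <- sweep_feedforward(lin$X[tr, ], lin$Y[tr, , drop = FALSE],
                            lin$X[te, ], lin$Y[te, , drop = FALSE],
                            units = 50, dropouts = 0.1, epochs = 5, seed = 9)
  expect_equal(nrow(surf), 1L)
  direct <- fit_learned(decoder("feedforward", units = 50, dropout = 0.1,
                                epochs = 5, seed = 9),
                        lin$X[tr, ], lin$Y[tr, , drop = FALSE])
  expect_equal(surf$r2, r2_score(lin$Y[te, , drop = FALSE],
                                 predict(direct, lin$X[te, ])),
               tolerance = 1e-12)
  expect_error(sweep_feedforward(lin$X[tr, ], lin$Y[tr, , drop = FALSE],
                                 lin$X[te, ], lin$Y[te, , drop = FALSE],
                                 units = integer(0), dropouts = 0.1),
               class = "spikedecode_invalid_argument")
})

test_that("the sweep surface is flat on easy data (hyperparameter robustness)", {
  set.seed(48)
  sim <- simulate_cortical(n_neurons = 20, duration = 200, mean_rate = 5,
                           tuning_depth = 3, seed = 48)
  dm <- make_design_matrix(sim$binned, lag_spec(3, 1, 0))
  K <- nrow(dm$X); tr <- 1:floor(0.85 * K); te <- (floor(0.85 * K) + 1):K
  xs <- fit_scaler(dm$X[tr, ], "zscore")
  surf <- sweep_feedforward(apply_scaler(xs, dm$X[tr, ]), dm$Y[tr, ],
                            apply_scaler(xs, dm$X[te, ]), dm$Y[te, ],
                            units = c(100, 200, 400), dropouts = c(0, 0.2, 0.4),
                            epochs = 10, seed = 10)
  expect_equal(nrow(surf), 9L)
  expect_lt(diff(range(surf$r2)), 0.1)
})
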