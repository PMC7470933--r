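test_that("tuning curves peak where a neuron fires and are flat when it doesn't care", {
  set.seed(31)
  y <- matrix(runif(2000, 0, 10))
  in_cell <- y[, 1] > 4.8 & y[, 1] < 5.2
  counts <- cbind(ifelse(in_cell, 5L, 0L),       # fires only near y = 5
                  rpois(2000, 3))                # uniform firing
  m <- nb_fit(y, counts, grid_resolution = 25, smoothing_bandwidth = 0)
  peak <- which.max(m$tuning[1, ])
  expect_equal(m$grid$centers[peak, 1], 5, tolerance = 10 / 25)
  flat <- m$tuning[2, ]
  expect_lt((max(flat) - min(flat)) / mean(flat), 0.5)
})

test_that("posterior argmax matches exhaustive enumeration by dpois products", {
  set.seed(32)
  for (i in 1:5) {
    G <- 25; N <- sample(2:5, 1)
    tuning <- matrix(runif(N * G, 0.05, 6), N, G)
    prior <- runif(G); prior <- prior / sum(prior)
    grid <- list(edges = list(seq(0, 1, length.out = G + 1)),
                 centers = matrix(seq_len(G), ncol = 1), resolution = G, d = 1L)
    model <- structure(list(grid = grid, tuning = tuning, prior = prior,
                            transition_bandwidth = 1, smoothing_bandwidth = 0,
                            rate_floor = 0.01, n_neurons = N),
                       class = "naive_bayes_model")
    counts <- matrix(rpois(20 * N, 2), 20, N)
    got <- nb_decode(model, counts, return_posterior = TRUE)
    post <- attr(got, "posterior")
    oracle <- nb_enum_oracle(tuning, prior, counts)
    expect_equal(unname(post), unname(oracle), tolerance = 1e-10)
    expect_equal(rowSums(post), rep(1, 20), tolerance = 1e-12)
    expect_equal(as.vector(got), apply(oracle, 1, which.max))
  }
})

test_that("a degenerate prior forces its cell regardless of the counts", {
  G <- 10
  tuning <- matrix(runif(3 * G, 0.5, 5), 3, G)
  prior <- rep(1e-30, G); prior[7] <- 1; prior <- prior / sum(prior)
  grid <- list(edges = list(seq(0, 1, length.out = G + 1)),
               centers = matrix(seq_len(G), ncol = 1), resolution = G, d = 1L)
  model <- structure(list(grid = grid, tuning = tuning, prior = prior,
                          transition_bandwidth = 1, smoothing_bandwidth = 0,
                          rate_floor = 0.01, n_neurons = 3),
                     class = "naive_bayes_model")
  counts <- matrix(rpois(30, 3), 10, 3)
  expect_true(all(nb_decode(model, counts) == 7))
})

test_that("neurons combine additively in the log posterior", {
  set.seed(33)
  G <- 15
  tuning <- matrix(runif(2 * G, 0.1, 4), 2, G)
  prior <- rep(1 / G, G)
  grid <- list(edges = list(seq(0, 1, length.out = G + 1)),
               centers = matrix(seq_len(G), ncol = 1), resolution = G, d = 1L)
  mk <- function(tun) structure(
    list(grid = grid, tuning = tun, prior = prior, transition_bandwidth = 1,
         smoothing_bandwidth = 0, rate_floor = 0.01, n_neurons = nrow(tun)),
    class = "naive_bayes_model")
  n <- matrix(c(3L, 1L), 1, 2)
  lp_both <- log(attr(nb_decode(mk(tuning), n, return_posterior = TRUE), "posterior"))
  lp1 <- log(attr(nb_decode(mk(tuning[1, , drop = FALSE]),
                            n[, 1, drop = FALSE], return_posterior = TRUE), "posterior"))
  lp2 <- log(attr(nb_decode(mk(tuning[2, , drop = FALSE]),
                            n[, 2, drop = FALSE], return_posterior = TRUE), "posterior"))
  # joint log posterior = sum of per-neuron log posteriors + flat prior,
  # up to one normalising constant per row
  comb <- lp1 + lp2
  expect_lt(diff(range(lp_both - comb)), 1e-10)
})

test_that("with a flat prior and one neuron the decoder inverts the tuning curve", {
  G <- 40
  tuning <- matrix(seq(0.1, 8, length.out = G), 1, G)   # monotone tuning
  grid <- list(edges = list(seq(0, 1, length.out = G + 1)),
               centers = matrix(seq_len(G), ncol = 1), resolution = G, d = 1L)
  model <- structure(list(grid = grid, tuning = tuning, prior = rep(1 / G, G),
                          transition_bandwidth = 1, smoothing_bandwidth = 0,
                          rate_floor = 0.01, n_neurons = 1),
                     class = "naive_bayes_model")
  for (n in c(0L, 2L, 5L, 9L)) {
    got <- drop(nb_decode(model, matrix(n)))
    ml <- which.max(n * log(tuning[1, ]) - tuning[1, ])
    expect_equal(got, ml)
  }
})

test_that("a simulated Gaussian place field is recovered within one grid cell", {
  sim <- simulate_hippocampal(n_neurons = 25, duration = 2000, seed = 34)
  wc <- window_counts(sim$binned, lag_spec(4, 1, 5))
  m <- nb_fit(wc$Y, wc$counts, grid_resolution = 20)
  cell <- 1 / 20
  active <- which(colSums(wc$counts) >= 100)   # identifiable fields only
  expect_gt(length(active), 5)
  peaks <- m$grid$centers[apply(m$tuning[active, , drop = FALSE], 1, which.max), ,
                          drop = FALSE]
  err <- sqrt(rowSums((peaks - sim$ground_truth$mu[active, , drop = FALSE])^2))
  expect_lt(median(err), sqrt(2) * cell)
})

test_that("the transition prior keeps successive estimates nearby", {
  sim <- simulate_hippocampal(n_neurons = 30, duration = 1500, seed = 35)
  wc <- window_counts(sim$binned, lag_spec(4, 1, 5))
  tr <- 1:6000; te <- 6001:nrow(wc$counts)
  m <- nb_fit(wc$Y[tr, ], wc$counts[tr, ])
  p_free <- nb_decode(m, wc$counts[te, ])
  p_tran <- nb_decode(m, wc$counts[te, ], use_transition_prior = TRUE)
  jump <- function(p) mean(sqrt(rowSums(apply(p, 2, diff)^2)))
  expect_lt(jump(p_tran), jump(p_free))
  expect_gte(r2_score(wc$Y[te, ], p_tran), r2_score(wc$Y[te, ], p_free) - 0.02)
})

test_that("nb_fit validates inputs", {
  expect_error(nb_fit(matrix(numeric(0), 0, 1), matrix(numeric(0), 0, 2)),
               class = "spikedecode_insufficient_data")
  expect_error(nb_fit(matrix(rnorm(30), 10, 3), matrix(0L, 10, 2)),
               class = "spikedecode_invalid_argument")
})
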