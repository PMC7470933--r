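test_that("bin_spikes counts spikes into half-open bins and drops the remainder", {
  sd1 <- spike_data(list(c(0.02, 0.07, 0.12)), duration = 0.15)
  expect_equal(unname(bin_spikes(sd1, 0.05)[, 1]), c(1L, 1L, 1L))

  sd2 <- spike_data(list(c(0.02, 0.07, 0.12), numeric(0)), duration = 0.15)
  expect_equal(unname(bin_spikes(sd2, 0.05)[, 2]), c(0L, 0L, 0L))

  # boundary spike belongs to the later bin
  sd3 <- spike_data(list(c(0.05)), duration = 0.15)
  expect_equal(unname(bin_spikes(sd3, 0.05)[, 1]), c(0L, 1L, 0L))

  # trailing partial bin dropped but conservation holds
  set.seed(42)
  times <- sort(runif(200, 0, 0.93))
  sd4 <- spike_data(list(times), duration = 0.93)
  counts <- bin_spikes(sd4, 0.1)
  expect_equal(nrow(counts), 9L)
  dropped <- sum(times >= 0.9)
  expect_equal(sum(counts) + dropped, 200L)
})

test_that("bin_spikes and spike_data validate their inputs", {
  expect_error(spike_data(list(c(0.3, 0.1)), 1), class = "spikedecode_invalid_input")
  expect_error(spike_data(list(c(0.3, 1.2)), 1), class = "spikedecode_invalid_input")
  sd1 <- spike_data(list(c(0.1)), 1)
  expect_error(bin_spikes(sd1, 0), class = "spikedecode_invalid_argument")
  expect_error(bin_spikes(sd1, -1), class = "spikedecode_invalid_argument")
})

test_that("bin_output averages within-bin samples and interpolates gaps", {
  # constant output
  out <- bin_output(seq(0.01, 0.99, by = 0.01), rep(3.5, 99), 0.1, 1)
  expect_true(all(out == 3.5))

  # mean of two samples in a single bin
  out2 <- bin_output(c(0.01, 0.04), c(0, 2), 0.05, 0.05)
  expect_equal(unname(drop(out2)), 1.0)

  # 3 samples per bin of a linear ramp vs a direct per-bin averaging oracle
  t <- seq(0.005, 0.995, length.out = 60)
  v <- 2 * t + 1
  got <- bin_output(t, v, 0.05, 1)
  oracle <- vapply(0:19, function(b) mean(v[t >= b * 0.05 & t < (b + 1) * 0.05]),
                   numeric(1))
  expect_equal(drop(got), oracle, tolerance = 1e-12)

  # an empty bin is filled by linear interpolation of its neighbours
  out3 <- bin_output(c(0.02, 0.22), c(1, 3), 0.1, 0.3)
  expect_equal(drop(out3), c(1, 2, 3))

  expect_error(bin_output(numeric(0), numeric(0), 0.1, 1),
               class = "spikedecode_invalid_input")
})

test_that("design matrix matches the hand-built lagged layout", {
  ds <- binned_dataset(matrix(1:8, 4, 2), matrix(rnorm(4)), 0.05)
  dm <- make_design_matrix(ds, lag_spec(1, 1, 0))
  expect_equal(nrow(dm$X), 3L)
  expect_equal(ncol(dm$X), 4L)
  expect_equal(dm$row_to_bin, 2:4)
  # row for output bin 2: all neurons at lag -1, then all neurons at lag 0
  expect_equal(unname(dm$X[1, ]), c(1, 5, 2, 6))
  expect_equal(dm$Y, ds$outputs[2:4, , drop = FALSE])
})

test_that("paper-style lag configurations give the stated B and exclusions", {
  expect_equal(lag_spec(13, 1, 0)$B, 14L)
  lg <- lag_spec(4, 1, 5)
  expect_equal(lg$B, 10L)
  ds <- random_binned(n_bins = 30)
  dm <- make_design_matrix(ds, lg)
  expect_equal(nrow(dm$X), 30L - 4L - 5L)
  expect_equal(dm$row_to_bin, 5:25)
})

test_that("sequence tensor flattens to the design matrix for random shapes", {
  for (seed in 1:6) {
    set.seed(seed)
    N <- sample(1:5, 1); nb <- sample(6:15, 1)
    before <- sample(0:3, 1); after <- sample(0:2, 1); cur <- sample(0:1, 1)
    if (before + cur + after == 0) cur <- 1
    if (nb <= before + after) nb <- before + after + 3
    ds <- random_binned(n_bins = nb, N = N, seed = seed)
    lg <- lag_spec(before, cur, after)
    dm <- make_design_matrix(ds, lg)
    st <- make_sequence_tensor(ds, lg)
    expect_equal(dim(st$X3), c(nrow(dm$X), N, lg$B))
    expect_equal(flatten_tensor(st), unname(dm$X))
    expect_equal(nrow(dm$X) + before + after, nb)
    # X3[k, :, j] equals the counts at bin row_to_bin[k] + offset_j
    k <- sample(nrow(dm$X), 1); j <- sample(lg$B, 1)
    expect_equal(st$X3[k, , j],
                 unname(ds$counts[st$row_to_bin[k] + lg$offsets[j], ]))
  }
})

test_that("B = 1 tensor is the concurrent count matrix", {
  ds <- random_binned(n_bins = 12, N = 4)
  st <- make_sequence_tensor(ds, lag_spec(0, 1, 0))
  expect_equal(st$X3[, , 1], unname(ds$counts))
})

test_that("window longer than the recording is rejected", {
  ds <- random_binned(n_bins = 5)
  expect_error(make_design_matrix(ds, lag_spec(3, 1, 2)),
               class = "spikedecode_invalid_argument")
})

test_that("scaler learns on training rows only and round-trips", {
  set.seed(7)
  train <- matrix(rnorm(200, mean = 5, sd = 3), 50, 4)
  test <- matrix(rnorm(80, mean = 9, sd = 2), 20, 4)
  sc <- fit_scaler(train, "zscore")
  zt <- apply_scaler(sc, train)
  expect_equal(colMeans(zt), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(zt, 2, sd), rep(1, 4), tolerance = 1e-12)
  # stored parameters reused verbatim on other rows: means move away from 0
  expect_gt(max(abs(colMeans(apply_scaler(sc, test)))), 0.5)
  expect_equal(invert_scaler(sc, apply_scaler(sc, test)), test, tolerance = 1e-12)

  cc <- fit_scaler(train, "center")
  expect_equal(colMeans(apply_scaler(cc, train)), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(apply_scaler(cc, train), 2, sd), apply(train, 2, sd))

  expect_warning(sz <- fit_scaler(cbind(train[, 1], 2), "zscore"), "zero-variance")
  expect_equal(sz$scale[2], 1)
})
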