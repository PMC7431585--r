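# Channel/trial rejection, re-referencing, downsampling.

test_that("kurtosis screening flags spiky channels but honors protection", {
  e <- make_noise_epochs(n_ch = 8, n_samples = 2000, n_trials = 2, seed = 21)
  out <- reject_channels_kurtosis(e)
  expect_length(out$report$rejected_channels, 0)
  expect_identical(out$epochs$channels, e$channels)

  # replace one channel with sparse large spikes: huge kurtosis
  spiky <- e
  v <- rep(0, 2000 * 2)
  v[seq(1, length(v), by = 400)] <- 80
  spiky$data[3, , ] <- v + rnorm(length(v), sd = 0.1)
  out2 <- reject_channels_kurtosis(spiky)
  expect_identical(out2$report$rejected_channels, e$channels[3])
  expect_identical(out2$epochs$channels, e$channels[-3])

  out3 <- reject_channels_kurtosis(spiky, protected = e$channels[3])
  expect_length(out3$report$rejected_channels, 0)
})

test_that("average re-reference zeroes the channel mean at every sample", {
  e <- make_noise_epochs(n_ch = 5, n_samples = 100, n_trials = 3, seed = 22,
                         channels = c("PO7", "PO8", "Cz", "P5", "P6"))
  r <- rereference_average(e)
  expect_equal(max(abs(colMeans(r$data))), 0, tolerance = 1e-12)
  # constant channels [2, 0] become [1, -1]
  e2 <- eeg_epochs(array(c(2, 0), c(2, 1, 1))[, rep(1, 10), , drop = FALSE],
                   500, 0, c("A1", "A2"))
  dim(e2$data) <- c(2, 10, 1)
  r2 <- rereference_average(e2)
  expect_equal(unique(as.vector(r2$data[1, , ])), 1)
  expect_equal(unique(as.vector(r2$data[2, , ])), -1)
  # already mean-zero input ([1, -1] constant channels) is untouched
  d3 <- array(0, c(2, 10, 1)); d3[1, , ] <- 1; d3[2, , ] <- -1
  e3 <- eeg_epochs(d3, 500, 0, c("A1", "A2"))
  expect_equal(rereference_average(e3)$data, e3$data)
  expect_error(rereference_average(
    eeg_epochs(array(0, c(1, 4, 1)), 500, 0, "Cz")), "2 channels")
})

test_that("iterative trial rejection removes outliers and is idempotent", {
  e <- make_noise_epochs(n_ch = 2, n_samples = 200, n_trials = 101, seed = 23,
                         channels = c("P5", "P6"))
  e$data[1, 50, 101] <- 1e6  # beyond the absolute limit outright
  out <- reject_trials_iterative(e)
  expect_identical(out$report$rejected_trials, 101L)
  expect_identical(dim(out$epochs$data)[3], 100L)
  # rejection never modifies retained values
  expect_identical(out$epochs$data, e$data[, , 1:100])
  # idempotent on its own output
  again <- reject_trials_iterative(out$epochs)
  expect_length(again$report$rejected_trials, 0)
  expect_identical(again$epochs$data, out$epochs$data)
})

test_that("the per-iteration cap forces multiple iterations", {
  e <- make_noise_epochs(n_ch = 1, n_samples = 100, n_trials = 100, seed = 24,
                         channels = "POz")
  e$data[1, 10, 1:10] <- 2000  # ten absolute-limit violations
  out <- reject_trials_iterative(e, max_frac_per_iter = 0.05)
  expect_true(all(1:10 %in% out$report$rejected_trials))
  expect_gte(out$report$iterations, 2)
  # all-equal trials: nothing to reject, single pass
  e2 <- eeg_epochs(array(1, c(1, 10, 5)), 500, 0, "Cz")
  out2 <- reject_trials_iterative(e2)
  expect_length(out2$report$rejected_trials, 0)
  expect_identical(out2$report$iterations, 1L)
})

test_that("downsampling halves the sample count and preserves content", {
  n <- 8500
  tms <- seq(0, by = 1, length.out = n)  # 1000 Hz
  sine <- sin(2 * pi * 10 * tms / 1000)
  dat <- array(0, c(2, n, 1))
  dat[1, , 1] <- 5          # DC
  dat[2, , 1] <- sine       # 10 Hz
  e <- eeg_epochs(dat, 1000, -1000, c("Cz", "Pz"))
  r <- downsample(e, 500)
  expect_equal(dim(r$data)[2], 4250)
  expect_equal(r$srate, 500)
  expect_equal(r$t0_ms, -1000)
  expect_equal(as.vector(r$data[1, , 1]), rep(5, 4250), tolerance = 0.01)
  # 10 Hz amplitude preserved within 1% away from the epoch edges
  kept <- 200:4000
  ref <- sine[seq(1, n, by = 2)][kept]
  expect_lt(max(abs(r$data[2, kept, 1] - ref)), 0.01)
  expect_error(downsample(e, 300), "integer")
})
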