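# Ipsi/contra assignment and the Alpha Lateralization Index.

make_tf <- function(power, channels, freqs = NULL, times = NULL) {
  d <- dim(power)
  tf_power(power, freqs %||% seq_len(d[2]), times %||% seq_len(d[3]) * 100,
           channels)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

trial_row <- function(precue_side, retrocue, probe = "cued") {
  data.frame(trial_id = 1L, block = 1L, precue_side = precue_side,
             retrocue = retrocue, probe = probe, response = "none",
             rt_ms = NA_real_, correct = NA, rejected = FALSE,
             stringsAsFactors = FALSE)
}

test_that("the lateralized item sits on the pre-cued side in every condition", {
  expect_equal(lateral_side(trial_row("left", "mi")), "left")
  expect_equal(lateral_side(trial_row("right", "bei")), "right")
  expect_equal(lateral_side(trial_row("left", "li")), "left")
})

test_that("ipsi/contra assignment follows the definition on a single trial", {
  ch <- unlist(default_cluster_pairs())  # PO7 PO8 P7 P8 P5 P6 PO3 PO4
  pw <- array(0, c(8, 2, 3, 1))
  left_ch <- c("PO7", "P7", "P5", "PO3")
  pw[match(left_ch, ch), , , 1] <- 1:24          # left hemisphere values
  pw[match(setdiff(ch, left_ch), ch), , , 1] <- 100 + (1:24)
  tf <- make_tf(pw, ch)
  tr <- trial_row("left", "li")
  out <- ipsi_contra_power(tf, tr, condition = "target_lateral")
  lmean <- apply(pw[match(left_ch, ch), , , 1], c(2, 3), mean)
  rmean <- apply(pw[match(setdiff(ch, left_ch), ch), , , 1], c(2, 3), mean)
  expect_equal(out$ipsi, lmean)
  expect_equal(out$contra, rmean)
  # a right-side trial swaps the roles
  out_r <- ipsi_contra_power(tf, trial_row("right", "re"),
                             condition = "target_lateral")
  expect_equal(out_r$ipsi, rmean)
  expect_equal(out_r$contra, lmean)
})

test_that("balanced opposite-side trials symmetrize ipsi and contra", {
  # two trials with identical data but opposite item sides: the hemisphere
  # roles swap between trials, so the trial-averaged ipsi and contra are
  # equal and the resulting ALI is zero
  ch <- unlist(default_cluster_pairs())
  set.seed(31)
  base <- array(runif(8 * 3 * 4), c(8, 3, 4))
  pw <- array(0, c(8, 3, 4, 2))
  pw[, , , 1] <- base
  pw[, , , 2] <- base
  tf <- make_tf(pw, ch)
  trials <- rbind(trial_row("left", "li"), trial_row("right", "re"))
  trials$trial_id <- 1:2
  out <- ipsi_contra_power(tf, trials, condition = "target_lateral")
  expect_equal(out$ipsi, out$contra)
  expect_equal(compute_ali(out$ipsi, out$contra), matrix(0, 3, 4))
})

test_that("the ALI ratio follows its closed form and handles zero power", {
  expect_equal(compute_ali(matrix(2), matrix(2)), matrix(0))
  expect_equal(compute_ali(matrix(3), matrix(1)), matrix(0.5))
  expect_equal(compute_ali(matrix(1), matrix(3)), matrix(-0.5))
  expect_equal(compute_ali(matrix(0), matrix(0)), matrix(0))
  m <- matrix(runif(12), 3)
  expect_true(all(abs(compute_ali(m, matrix(runif(12), 3))) <= 1))
  expect_error(compute_ali(matrix(1), matrix(1:2, 1)), "shapes")
  expect_error(compute_ali(matrix(-1), matrix(1)), "non-negative")
})

test_that("window means average the right grid points, inclusively", {
  freqs <- seq(4, 30, length.out = 27)   # integer Hz steps
  times <- seq(3000, 5000, length.out = 21)
  m <- matrix(7, 27, 21)
  expect_equal(window_mean(m, freqs, times), 7)
  # +1 inside the band/window, -1 outside
  fi <- freqs >= 8 & freqs <= 13         # 6 frequencies
  ti <- times >= 3700 & times <= 4300    # 7 time points
  m2 <- matrix(-1, 27, 21); m2[fi, ti] <- 1
  expect_equal(window_mean(m2, freqs, times), 1)
  # checkerboard over an even number of window points averages to zero
  m3 <- matrix(0, 27, 21)
  m3[fi, ti] <- rep_len(c(1, -1), sum(fi) * sum(ti))
  expect_equal(window_mean(m3, freqs, times), 0)
  expect_error(window_mean(m, freqs, times, band = c(40, 50)), "intersect")
})

test_that("swapping hemispheres negates the ALI; swapping both restores it", {
  ch <- unlist(default_cluster_pairs())
  fam <- build_wavelet_family(n_steps = 12)
  p <- sim_params(n_trials = 16, ali_target = 0.3, seed = 33)
  d <- generate_design(16, seed = 33)
  e <- simulate_eeg(d, p)
  swap <- c(2, 1, 4, 3, 6, 5, 8, 7, 9, 10, 11, 12)
  e_swapped <- eeg_epochs(e$data[swap, , , drop = FALSE], e$srate, e$t0_ms,
                          e$channels)
  d_flipped <- d
  d_flipped$precue_side <- ifelse(d$precue_side == "left", "right", "left")
  d_flipped$retrocue[d$retrocue == "li"] <- "re"
  d_flipped$retrocue[d$retrocue == "re"] <- "li"

  ali_fun <- function(ep, tab) {
    tf <- morlet_power(ep, fam, channels = ch, time_grid = 60)
    subject_ali(tf, tab)$target_lateral$ali
  }
  a0 <- ali_fun(e, d)
  # swapping only the channel data negates the index ...
  expect_equal(ali_fun(e_swapped, d), -a0, tolerance = 1e-9)
  # ... swapping data and trial sides leaves it unchanged
  expect_equal(ali_fun(e_swapped, d_flipped), a0, tolerance = 1e-9)
})

test_that("conditions without retained trials are an explicit error", {
  ch <- unlist(default_cluster_pairs())
  pw <- array(1, c(8, 2, 2, 1))
  tf <- make_tf(pw, ch)
  tr <- trial_row("left", "li")
  expect_error(ipsi_contra_power(tf, tr, condition = "neutral"),
               "neutral")
  tr$rejected <- TRUE
  expect_error(ipsi_contra_power(tf, tr, condition = "target_lateral"),
               "no retained trials")
})
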