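# Complex Morlet wavelet decomposition on a log-spaced frequency grid,
# producing raw (non-baseline-corrected) spectral power: the lateralization
# index downstream is a ratio of raw power values, so no baseline mode exists.

#' Cycle count of the wavelet at a given frequency
#'
#' The number of cycles grows linearly with frequency between the two
#' configured endpoints: `c(f) = c_min + (c_max - c_min) * (f - f_min) /
#' (f_max - f_min)`, honoring both printed endpoints (3 cycles at 4 Hz,
#' 11.25 cycles at 30 Hz by default).
#'
#' @param f frequency (Hz), vectorized.
#' @param f_min,f_max frequency range endpoints (Hz).
#' @param c_min,c_max cycle counts at `f_min` and `f_max`.
#' @return numeric vector of cycle counts.
#' @examples
#' wavelet_cycles(17) # 7.125
#' @export
wavelet_cycles <- function(f, f_min = 4, f_max = 30, c_min = 3,
                           c_max = 11.25) {
  c_min + (c_max - c_min) * (f - f_min) / (f_max - f_min)
}

#' Build a Morlet wavelet family
#'
#' Center frequencies form a geometric (log-spaced) sequence of `n_steps`
#' values from `f_min` to `f_max` inclusive; the cycle count grows linearly
#' in frequency between `c_min` and `c_max` (see [wavelet_cycles()]). Each
#' wavelet is a Gaussian-windowed complex exponential with temporal width
#' `sigma_t = cycles / (2 * pi * f)`, truncated at 3 sigma and normalized to
#' unit energy, so power is comparable across frequencies up to a
#' family-constant factor.
#'
#' @param f_min,f_max frequency range (Hz); `f_max` must be below Nyquist.
#' @param n_steps number of center frequencies (default 52).
#' @param c_min,c_max cycles at the lowest / highest frequency
#'   (defaults 3 and 11.25).
#' @param srate sampling rate of the data to be analyzed (Hz).
#' @return An object of class `wavelet_family`: list with `freqs`, `cycles`,
#'   `srate`.
#' @export
build_wavelet_family <- function(f_min = 4, f_max = 30, n_steps = 52,
                                 c_min = 3, c_max = 11.25, srate = 500) {
  if (f_min >= f_max) stop_fmt("f_min must be below f_max")
  if (n_steps < 2) stop_fmt("need at least 2 frequency steps")
  if (c_min > c_max) stop_fmt("c_min must not exceed c_max")
  if (f_max >= srate / 2) stop_fmt("f_max (%g Hz) must be below Nyquist (%g Hz)",
                                   f_max, srate / 2)
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_steps))
  freqs[c(1L, n_steps)] <- c(f_min, f_max)  # endpoints exact
  structure(list(freqs = freqs,
                 cycles = wavelet_cycles(freqs, f_min, f_max, c_min, c_max),
                 srate = srate),
            class = "wavelet_family")
}

#' @export
print.wavelet_family <- function(x, ...) {
  cat(sprintf("<wavelet_family> %d frequencies, %g-%g Hz (log-spaced), %g-%g cycles, srate %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$cycles[1L], x$cycles[length(x$cycles)], x$srate))
  invisible(x)
}

# Sampled complex Morlet wavelet, truncated at +/- 3 sigma_t, unit energy.
morlet_taps <- function(f, cycles, srate) {
  sigma_t <- cycles / (2 * pi * f)
  hs <- ceiling(3 * sigma_t * srate)
  t <- (-hs:hs) / srate
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Time-frequency power container
#'
#' @param power non-negative array, channel x frequency x time x trial.
#' @param freqs,times axis vectors (Hz, ms).
#' @param channels channel labels.
#' @return object of class `tf_power`.
#' @export
tf_power <- function(power, freqs, times, channels) {
  d <- dim(power)
  stopifnot(length(d) == 4L, d[1L] == length(channels),
            d[2L] == length(freqs), d[3L] == length(times))
  if (min(power) < 0) stop_fmt("power must be non-negative")
  structure(list(power = power, freqs = freqs, times = times,
                 channels = channels), class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tf_power> %d channels x %d freqs (%g-%g Hz) x %d times (%g-%g ms) x %d trials\n",
              d[1L], d[2L], min(x$freqs), max(x$freqs), d[3L],
              min(x$times), max(x$times), d[4L]))
  invisible(x)
}

#' Morlet wavelet power of epoched EEG
#'
#' Convolves every channel/trial signal with each wavelet of the family and
#' returns squared magnitudes — raw power, no baseline correction — sampled
#' at `time_grid` evenly spaced points across the retained span
#' `[t_min, t_max]`. The retained span must keep clear of the epoch edges by
#' half the support of the widest (lowest-frequency) wavelet, so no returned
#' value is contaminated by edge effects; the defaults trim the native
#' -1000..7500 ms epoch to -582..7080 ms.
#'
#' @param epochs an [eeg_epochs] object.
#' @param family a [build_wavelet_family()] object (srate must match).
#' @param channels channels to decompose (default: all).
#' @param time_grid number of evenly spaced output time points (default 200).
#' @param t_min,t_max retained time span in ms (defaults -582 and 7080).
#' @return A [tf_power] object (channel x frequency x time x trial).
#' @export
morlet_power <- function(epochs, family, channels = NULL, time_grid = 200,
                         t_min = -582, t_max = 7080) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(family, "wavelet_family"))
  if (!isTRUE(all.equal(family$srate, epochs$srate)))
    stop_fmt("wavelet family srate (%g) != epoch srate (%g)",
             family$srate, epochs$srate)
  channels <- channels %||% epochs$channels
  ep <- subset_channels(epochs, channels)
  d <- dim(ep$data)
  n_samples <- d[2L]
  t_ms <- epoch_times(ep)

  taps <- lapply(seq_along(family$freqs), function(i)
    morlet_taps(family$freqs[i], family$cycles[i], family$srate))
  half <- vapply(taps, function(w) (length(w) - 1L) %/% 2L, integer(1))
  if (2L * max(half) + 1L > n_samples)
    stop_fmt("epoch (%d samples) shorter than the widest wavelet (%d taps)",
             n_samples, 2L * max(half) + 1L)
  margin_ms <- max(half) * 1000 / family$srate
  lo <- t_ms[1L] + margin_ms
  hi <- t_ms[n_samples] - margin_ms
  if (t_min < lo - 1e-6 || t_max > hi + 1e-6)
    stop_fmt("retained span [%g, %g] ms reaches into the wavelet edge region; valid span is [%.1f, %.1f] ms",
             t_min, t_max, lo, hi)
  grid_ms <- seq(t_min, t_max, length.out = time_grid)
  grid_idx <- round((grid_ms - t_ms[1L]) * family$srate / 1000) + 1L

  # The convolution is needed only at the grid points, so evaluate the
  # wavelet inner products directly there: all wavelets are zero-padded to
  # the widest support, the signal segments under the grid points are
  # gathered once, and all frequencies are contracted in a single real
  # matrix product (power is phase-insensitive, so correlation vs.
  # convolution orientation does not matter). Trials are processed in
  # chunks to bound the size of the gathered segment matrix.
  nf <- length(family$freqs)
  H <- max(half)
  K <- 2L * H + 1L
  W <- matrix(0, 2L * nf, K)                 # rows: Re(f1..fnf), Im(f1..fnf)
  for (fi in seq_len(nf)) {
    span <- (H - half[fi] + 1L):(H + half[fi] + 1L)
    W[fi, span] <- Re(taps[[fi]])
    W[nf + fi, span] <- Im(taps[[fi]])
  }
  idx <- as.vector(outer(seq(-H, H), grid_idx, "+"))        # K x grid

  out <- array(0, c(d[1L], nf, time_grid, d[3L]))
  chunk <- max(1L, floor(4e7 / (K * time_grid * d[1L])))    # trials per pass
  for (start in seq(1L, d[3L], by = chunk)) {
    trs <- start:min(start + chunk - 1L, d[3L])
    nct <- d[1L] * length(trs)
    X <- matrix(aperm(ep$data[, , trs, drop = FALSE], c(2L, 1L, 3L)),
                n_samples, nct)
    S <- X[idx, , drop = FALSE]                             # (K*grid) x nct
    dim(S) <- c(K, time_grid * nct)
    P <- W %*% S                                            # 2nf x grid*nct
    p <- P[seq_len(nf), , drop = FALSE]^2 +
      P[nf + seq_len(nf), , drop = FALSE]^2
    dim(p) <- c(nf, time_grid, d[1L], length(trs))
    out[, , , trs] <- aperm(p, c(3L, 1L, 2L, 4L))
  }
  tf_power(out, family$freqs, grid_ms, ep$channels)
}
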