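# Artifact handling: robust kurtosis-based channel screening, average
# re-reference, iterative SD-threshold trial rejection, and integer-factor
# downsampling. The band-pass filtering / ICA stages of a full lab pipeline
# are intentionally absent: data enter this module already band-limited.

new_rejection_report <- function(rejected_channels = character(),
                                 rejected_trials = integer(),
                                 iterations = 1L, thresholds = list()) {
  structure(list(rejected_channels = rejected_channels,
                 rejected_trials = rejected_trials,
                 iterations = iterations, thresholds = thresholds),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("<rejection_report>\n")
  cat(sprintf("  channels rejected: %s\n",
              if (length(x$rejected_channels))
                paste(x$rejected_channels, collapse = ", ") else "none"))
  cat(sprintf("  trials rejected:   %d\n", length(x$rejected_trials)))
  cat(sprintf("  iterations:        %d\n", x$iterations))
  invisible(x)
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}

#' Reject channels by trimmed-normalized kurtosis
#'
#' Computes the excess kurtosis of each channel's concatenated signal and
#' z-scores the values against a robust location/scale estimated after
#' trimming the stated proportion of extreme kurtosis values from each end
#' of the across-channel distribution (so the very outliers being screened
#' for do not inflate the normalization). Channels whose |z| exceeds
#' `z_thresh` are removed, except those in `protected` (e.g. anterior
#' lateral channels kept for ocular monitoring).
#'
#' @param epochs an [eeg_epochs] object.
#' @param trim proportion trimmed from each end of the kurtosis distribution
#'   before estimating its mean and SD (default 0.2).
#' @param z_thresh rejection threshold in SD units (default 5).
#' @param protected character vector of labels exempt from rejection.
#' @return A list with the cleaned `epochs` and a `rejection_report`.
#' @export
reject_channels_kurtosis <- function(epochs, trim = 0.2, z_thresh = 5,
                                     protected = character()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (trim < 0 || trim >= 0.5) stop_fmt("`trim` must lie in [0, 0.5)")
  if (z_thresh <= 0) stop_fmt("`z_thresh` must be positive")
  n_ch <- dim(epochs$data)[1L]
  k <- vapply(seq_len(n_ch),
              function(c) excess_kurtosis(as.vector(epochs$data[c, , ])),
              numeric(1))
  ks <- sort(k)
  cut <- floor(trim * n_ch)
  core <- if (cut > 0) ks[(cut + 1):(n_ch - cut)] else ks
  mu <- mean(core)
  sd0 <- stats::sd(core)
  z <- if (sd0 > 0) (k - mu) / sd0 else numeric(n_ch)
  drop <- abs(z) > z_thresh & !(epochs$channels %in% protected)
  if (all(drop)) stop_fmt("all channels would be rejected")
  report <- new_rejection_report(
    rejected_channels = epochs$channels[drop],
    thresholds = list(trim = trim, z_thresh = z_thresh, kurtosis = k, z = z))
  list(epochs = subset_channels(epochs, epochs$channels[!drop]),
       report = report)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample of every trial, the mean across all retained
#' channels, so the across-channel mean of the output is identically zero.
#'
#' @param epochs an [eeg_epochs] object with at least two channels.
#' @return A re-referenced [eeg_epochs] object.
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[1L] < 2L)
    stop_fmt("average re-reference needs at least 2 channels")
  mu <- colMeans(epochs$data)           # sample x trial
  data <- epochs$data
  for (c in seq_len(dim(data)[1L])) data[c, , ] <- data[c, , ] - mu
  eeg_epochs(data, epochs$srate, epochs$t0_ms, epochs$channels)
}

#' Iterative SD-threshold trial rejection
#'
#' Flags trials containing any sample whose value lies more than `z_thresh`
#' standard deviations from the across-trial mean of that channel-sample, or
#' beyond the absolute `abs_limit`. At most `max_frac_per_iter` of the
#' remaining trials are removed per iteration (worst offenders first, by
#' peak |z|, with absolute-limit violations ranked ahead), the across-trial
#' statistics are recomputed, and the procedure repeats until no trial
#' exceeds threshold. The operation is idempotent on its own output.
#'
#' @param epochs an [eeg_epochs] object.
#' @param z_thresh SD threshold (default 5).
#' @param abs_limit absolute voltage limit in microvolts (default 1000).
#' @param max_frac_per_iter maximum fraction of remaining trials removed per
#'   iteration (default 0.05).
#' @param max_iter iteration cap; exceeding it is an error (default 100).
#' @return A list with the cleaned `epochs` and a `rejection_report` whose
#'   `rejected_trials` are indices into the input trial dimension.
#' @export
reject_trials_iterative <- function(epochs, z_thresh = 5, abs_limit = 1000,
                                    max_frac_per_iter = 0.05,
                                    max_iter = 100L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (z_thresh <= 0) stop_fmt("`z_thresh` must be positive")
  if (max_frac_per_iter <= 0 || max_frac_per_iter > 1)
    stop_fmt("`max_frac_per_iter` must lie in (0, 1]")
  d <- dim(epochs$data)
  X <- matrix(epochs$data, d[1L] * d[2L], d[3L])  # (channel*sample) x trial
  keep <- seq_len(d[3L])
  rejected <- integer()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop_fmt("trial rejection did not converge in %d iterations (%d rejected)",
               max_iter, length(rejected))
    n <- length(keep)
    Xi <- X[, keep, drop = FALSE]
    mu <- rowMeans(Xi)
    s <- sqrt(pmax(rowSums((Xi - mu)^2) / (n - 1L), 0))
    s[s == 0] <- Inf
    z_peak <- apply(abs(Xi - mu) / s, 2L, max)
    v_peak <- apply(abs(Xi), 2L, max)
    bad <- z_peak > z_thresh | v_peak > abs_limit
    if (!any(bad)) break
    score <- z_peak + ifelse(v_peak > abs_limit, Inf, 0)
    cap <- max(1L, ceiling(max_frac_per_iter * n))
    victims <- order(-score)[seq_len(min(cap, sum(bad)))]
    rejected <- c(rejected, keep[victims])
    keep <- keep[-victims]
    if (!length(keep)) stop_fmt("all trials rejected")
  }
  report <- new_rejection_report(
    rejected_trials = sort(rejected), iterations = iter,
    thresholds = list(z_thresh = z_thresh, abs_limit = abs_limit,
                      max_frac_per_iter = max_frac_per_iter))
  list(epochs = subset_trials(epochs, keep), report = report)
}

#' Downsample epochs by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (8th-order Chebyshev type I,
#' 0.01 dB passband ripple, cutoff at 0.8 of the new Nyquist frequency, run
#' forwards and backwards) and then
#' keeps every q-th sample. Only integer rate ratios are supported; the
#' epoch time origin is preserved.
#'
#' @param epochs an [eeg_epochs] object.
#' @param new_srate target sampling rate; must divide `epochs$srate`.
#' @return A downsampled [eeg_epochs] object.
#' @export
downsample <- function(epochs, new_srate) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  q <- epochs$srate / new_srate
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop_fmt("srate ratio %g is not a positive integer", q)
  q <- as.integer(round(q))
  if (q == 1L) return(epochs)
  d <- dim(epochs$data)
  idx <- seq(1L, d[2L], by = q)
  filt <- signal::cheby1(8, 0.01, 0.8 / q)  # 0.01 dB ripple keeps DC flat
  out <- array(0, c(d[1L], length(idx), d[3L]))
  for (tr in seq_len(d[3L])) {
    for (c in seq_len(d[1L])) {
      y <- signal::filtfilt(filt, epochs$data[c, , tr])
      out[c, , tr] <- y[idx]
    }
  }
  eeg_epochs(out, new_srate, epochs$t0_ms, epochs$channels)
}
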