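# Synthetic study generator: trial-locked EEG with injected lateralized
# alpha modulations, and behavioral responses with retro-cue benefits.

#' Simulation parameters
#'
#' Collects and validates all knobs of the synthetic study generator. The
#' defaults reproduce the recorded study's conditions: 800 trials in blocks
#' of 100, 500 Hz sampling over an epoch from -1000 to 7500 ms around the
#' pre-cue, a 10 Hz alpha rhythm at the posterior electrode cluster over a
#' 1/f pink-noise background, and an attentional modulation confined to a
#' 700-1300 ms window after retro-cue onset. The injected Alpha
#' Lateralization Index (ALI) is positive for target-lateral cues
#' (contralateral alpha decrease), negative for distractor-lateral cues
#' (contralateral increase) and zero for neutral cues.
#'
#' @param n_trials trials per subject (multiple of 16; default 800).
#' @param srate sampling rate in Hz (default 500).
#' @param alpha_freq alpha carrier frequency in Hz (default 10).
#' @param noise_rms pink-noise RMS per channel in microvolts (default 5).
#' @param noise_exponent spectral exponent of the 1/f^a background (default 1).
#' @param alpha_amp baseline alpha amplitude at posterior channels, microvolts
#'   (default 10).
#' @param effect_window ms post retro-cue onset over which the lateralized
#'   modulation is active (default `c(700, 1300)`).
#' @param ramp_ms raised-cosine on/off ramp at the effect-window edges
#'   (default 100); avoids spectral splatter at the window borders.
#' @param ali_target,ali_distractor,ali_neutral injected ALI per condition
#'   (defaults +0.2, -0.2, 0); absolute values must be < 1.
#' @param bilateral_suppression optional fractional bilateral alpha power
#'   suppression after the retro-cue (default 0 = off); mirrors the
#'   non-lateralized post-cue alpha decrease without affecting the ALI.
#' @param rt_base_ms median response time of the neutral/new baseline
#'   (default 900).
#' @param rt_sdlog log-normal RT dispersion (default 0.25).
#' @param rt_benefit_ms RT advantage of selective over neutral retro-cues
#'   (default 60).
#' @param interference_ms RT cost of non-cued over new probes (default 40).
#' @param cued_advantage_ms RT advantage of cued over new probes (default 50).
#' @param accuracy_base probability of a correct response (default 0.9).
#' @param acc_interference accuracy drop for non-cued probes (default 0.08).
#' @param lapse_rate probability of a missing response (default 0.02).
#' @param channels channel labels to simulate; must contain the eight
#'   posterior cluster electrodes.
#' @param epoch_span epoch limits in ms around pre-cue onset
#'   (default `c(-1000, 7500)`).
#' @param seed default RNG seed used by the simulators.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_trials = 800, srate = 500, alpha_freq = 10,
                       noise_rms = 5, noise_exponent = 1, alpha_amp = 10,
                       effect_window = c(700, 1300), ramp_ms = 100,
                       ali_target = 0.2, ali_distractor = -0.2,
                       ali_neutral = 0, bilateral_suppression = 0,
                       rt_base_ms = 900, rt_sdlog = 0.25, rt_benefit_ms = 60,
                       interference_ms = 40, cued_advantage_ms = 50,
                       accuracy_base = 0.9, acc_interference = 0.08,
                       lapse_rate = 0.02,
                       channels = c("PO7", "PO8", "P7", "P8", "P5", "P6",
                                    "PO3", "PO4", "Pz", "POz", "Oz", "Cz"),
                       epoch_span = c(-1000, 7500), seed = 1) {
  p <- as.list(environment())
  ali <- c(ali_target, ali_distractor, ali_neutral)
  if (any(abs(ali) >= 1)) stop_fmt("|injected ALI| must be < 1")
  probs <- c(accuracy_base, acc_interference, lapse_rate,
             bilateral_suppression)
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must lie in [0, 1]")
  if (any(c(rt_base_ms, rt_benefit_ms, interference_ms, cued_advantage_ms,
            rt_sdlog) < 0))
    stop_fmt("RT parameters must be non-negative")
  if (accuracy_base - acc_interference < 0)
    stop_fmt("acc_interference cannot exceed accuracy_base")
  win <- RETROCUE_ONSET_MS + effect_window
  if (length(effect_window) != 2L || diff(effect_window) <= 0 ||
      win[1L] < epoch_span[1L] || win[2L] > epoch_span[2L])
    stop_fmt("effect window must be an increasing interval inside the epoch")
  if (any(c(srate, alpha_freq, noise_rms, alpha_amp, ramp_ms) < 0))
    stop_fmt("rates and amplitudes must be non-negative")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

# 1/f^a noise: shape white Gaussian noise in the frequency domain. The
# amplitude filter is symmetric in bin k <-> n-k, so the inverse transform is
# real up to rounding. Returns an n x m matrix scaled to `rms` per column.
pink_noise <- function(n, m, srate, exponent, rms) {
  w <- matrix(stats::rnorm(n * m), n, m)
  if (exponent == 0 || rms == 0) {
    if (rms == 0) return(matrix(0, n, m))
    return(w * rms)
  }
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * srate / n
  amp <- c(0, f[-1]^(-exponent / 2))  # drop DC
  x <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / n
  sds <- sqrt(colMeans(x^2))
  sweep(x, 2L, ifelse(sds > 0, rms / sds, 1), "*")
}

# Raised-cosine window: 0 outside [t1, t2], 1 on the plateau, half-cosine
# ramps of `ramp` ms just inside the edges.
ramp_window <- function(t, t1, t2, ramp) {
  w <- numeric(length(t))
  inside <- t >= t1 & t <= t2
  w[inside] <- 1
  if (ramp > 0) {
    up <- t >= t1 & t < t1 + ramp
    w[up] <- 0.5 * (1 - cos(pi * (t[up] - t1) / ramp))
    dn <- t > t2 - ramp & t <= t2
    w[dn] <- 0.5 * (1 - cos(pi * (t2 - t[dn]) / ramp))
  }
  w
}

#' Simulate epoched EEG with injected alpha lateralization
#'
#' Every channel carries pink (1/f) noise; the eight posterior cluster
#' electrodes additionally carry a `alpha_freq` Hz oscillation with a random
#' phase per trial. Within the post-retro-cue effect window the two
#' hemispheres' alpha amplitudes are rescaled to `sqrt(1 + ALI)` (ipsilateral
#' to the lateralized item) and `sqrt(1 - ALI)` (contralateral), so the
#' oscillation's expected power ratio is exactly `(1 - ALI)/(1 + ALI)`
#' contralateral over ipsilateral and the ALI of the injected signal equals
#' the condition's target value (the pink-noise floor in the alpha band
#' shrinks the *estimated* index toward zero; see the methods vignette).
#'
#' @param design a trial table from [generate_design()].
#' @param params a [sim_params] object.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return An [eeg_epochs] object, deterministic given the seed.
#' @export
simulate_eeg <- function(design, params = sim_params(), seed = params$seed) {
  validate_trial_table(design)
  stopifnot(inherits(params, "sim_params"))
  cluster <- unlist(default_cluster_pairs(), use.names = FALSE)
  missing_ch <- setdiff(cluster, params$channels)
  if (length(missing_ch))
    stop_fmt("simulated channel list lacks required cluster electrode(s): %s",
             paste(missing_ch, collapse = ", "))

  srate <- params$srate
  n_samples <- as.integer(round(diff(params$epoch_span) * srate / 1000))
  t_ms <- params$epoch_span[1L] + (seq_len(n_samples) - 1) * 1000 / srate
  n_trials <- nrow(design)
  n_ch <- length(params$channels)
  side_of <- channel_side(params$channels)
  is_cluster <- params$channels %in% cluster

  ali_of <- c(target_lateral = params$ali_target,
              distractor_lateral = params$ali_distractor,
              neutral = params$ali_neutral)
  cond <- retrocue_condition(design$retrocue)

  win <- RETROCUE_ONSET_MS + params$effect_window
  w_eff <- ramp_window(t_ms, win[1L], win[2L], params$ramp_ms)
  w_sup <- if (params$bilateral_suppression > 0)
    ramp_window(t_ms, RETROCUE_ONSET_MS + 200,
                max(t_ms) + 1, params$ramp_ms) else NULL

  with_seed(seed, {
    data <- array(0, c(n_ch, n_samples, n_trials))
    for (tr in seq_len(n_trials)) {
      x <- t(pink_noise(n_samples, n_ch, srate, params$noise_exponent,
                        params$noise_rms))
      phase <- stats::runif(1, 0, 2 * pi)
      carrier <- sin(2 * pi * params$alpha_freq * t_ms / 1000 + phase)
      a <- ali_of[[cond[tr]]]
      amp_ipsi <- sqrt(1 + a); amp_contra <- sqrt(1 - a)
      ipsi_side <- design$precue_side[tr]
      for (ci in which(is_cluster)) {
        gain <- if (side_of[ci] == ipsi_side) amp_ipsi else amp_contra
        env <- params$alpha_amp * (1 + (gain - 1) * w_eff)
        if (!is.null(w_sup))
          env <- env * sqrt(1 - params$bilateral_suppression * w_sup)
        x[ci, ] <- x[ci, ] + env * carrier
      }
      data[, , tr] <- x
    }
    eeg_epochs(data, srate, params$epoch_span[1L], params$channels)
  })
}

#' Simulate behavioral responses
#'
#' Response times are log-normal around `rt_base_ms` with additive condition
#' shifts: selective retro-cues are faster than neutral ones by
#' `rt_benefit_ms`; non-cued probes are slower than new probes by
#' `interference_ms`; cued probes are faster by `cued_advantage_ms`.
#' Correctness is Bernoulli with probability `accuracy_base`, lowered by
#' `acc_interference` for non-cued probes; a `lapse_rate` fraction of trials
#' has no response at all. Responses falling outside the valid 200 ms to
#' (1500 ms + probe duration) window are produced naturally by the RT tail
#' and are marked erroneous downstream, as are lapses.
#'
#' @inheritParams simulate_eeg
#' @return The design with `response`, `rt_ms` and `correct` filled in.
#' @export
simulate_behavior <- function(design, params = sim_params(),
                              seed = params$seed) {
  validate_trial_table(design)
  stopifnot(inherits(params, "sim_params"))
  n <- nrow(design)
  cond <- retrocue_condition(design$retrocue)
  selective <- cond != "neutral"
  with_seed(seed, {
    shift <- -params$rt_benefit_ms * selective +
      params$interference_ms * (design$probe == "noncued") -
      params$cued_advantage_ms * (design$probe == "cued")
    rt <- stats::rlnorm(n, log(params$rt_base_ms), params$rt_sdlog) + shift
    p_correct <- params$accuracy_base -
      params$acc_interference * (design$probe == "noncued")
    correct <- stats::runif(n) < p_correct
    lapse <- stats::runif(n) < params$lapse_rate
    truth <- ifelse(design$probe == "cued", "yes", "no")
    flip <- c(yes = "no", no = "yes")
    design$response <- ifelse(lapse, "none",
                              ifelse(correct, truth, flip[truth]))
    design$correct <- !lapse & correct
    design$rt_ms <- ifelse(design$response == "none", NA_real_, pmax(rt, 1))
    design
  })
}
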