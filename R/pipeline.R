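# End-to-end study driver: simulate subjects, decompose, compute ALI maps,
# then run the cluster permutation contrast and the follow-up statistics.

#' Simulate and analyze one subject
#'
#' Generates a trial design, behavioral responses and epoched EEG for one
#' subject, runs the Morlet decomposition over the posterior cluster
#' channels, and returns the per-condition ALI maps and window means.
#'
#' @param params a [sim_params] object.
#' @param seed subject-level seed.
#' @param family wavelet family (default: the full 4-30 Hz, 52-step family).
#' @param time_grid number of output time points (default 200).
#' @param preprocess logical; when `TRUE` the synthetic epochs additionally
#'   pass through average re-referencing and iterative trial rejection
#'   before decomposition (default `FALSE`: simulated data are clean).
#' @return list with `trials`, `ali` (an `ali_maps` object), and
#'   `window_means` (named length-3 vector).
#' @export
run_subject <- function(params = sim_params(), seed = params$seed,
                        family = build_wavelet_family(srate = params$srate),
                        time_grid = 200, preprocess = FALSE) {
  design <- generate_design(params$n_trials, seed = seed)
  trials <- simulate_behavior(design, params, seed = seed + 1L)
  epochs <- simulate_eeg(trials, params, seed = seed + 2L)
  if (preprocess) {
    epochs <- rereference_average(epochs)
    tr <- reject_trials_iterative(epochs)
    epochs <- tr$epochs
    if (length(tr$report$rejected_trials))
      trials$rejected[tr$report$rejected_trials] <- TRUE
    trials_used <- trials[!trials$rejected, , drop = FALSE]
  } else {
    trials_used <- trials
  }
  cluster_ch <- unlist(default_cluster_pairs(), use.names = FALSE)
  tf <- morlet_power(epochs, family, channels = cluster_ch,
                     time_grid = time_grid)
  ali <- subject_ali(tf, trials_used)
  wm <- vapply(c("target_lateral", "distractor_lateral", "neutral"),
               function(cd) ali[[cd]]$window_mean, numeric(1))
  list(trials = trials, ali = ali, window_means = wm)
}

#' Simulate and analyze a full study
#'
#' Runs [run_subject()] for `n_subjects` subjects (seeds `seed`, `seed +
#' 1000`, `seed + 2000`, ...), stacks the per-subject ALI maps, contrasts
#' target-lateral against distractor-lateral maps with the cluster-based
#' permutation test, and computes the follow-up window statistics and the
#' behavioral analysis.
#'
#' @inheritParams run_subject
#' @param n_subjects number of simulated subjects (default 20).
#' @param seed study-level seed.
#' @param n_perm permutation count for the cluster test (default 1000).
#' @param ... forwarded to [cluster_test()].
#' @return list of class `ali_study`: `window_means` (subject x condition
#'   matrix), `maps` (list of subject x freq x time arrays per condition),
#'   `cluster` (a `cluster_test`), `followup` (an `ali_followup`),
#'   `behavior` (a `behavior_analysis`), `freqs`, `times`.
#' @export
run_study <- function(n_subjects = 20, params = sim_params(), seed = 1,
                      family = build_wavelet_family(srate = params$srate),
                      time_grid = 200, n_perm = 1000, preprocess = FALSE,
                      ...) {
  subjects <- lapply(seq_len(n_subjects), function(s)
    run_subject(params, seed = seed + (s - 1L) * 1000L, family = family,
                time_grid = time_grid, preprocess = preprocess))
  conds <- c("target_lateral", "distractor_lateral", "neutral")
  nf <- length(family$freqs); nt <- time_grid
  maps <- lapply(conds, function(cd) {
    arr <- array(0, c(n_subjects, nf, nt))
    for (s in seq_len(n_subjects)) arr[s, , ] <- subjects[[s]]$ali[[cd]]$ali
    arr
  })
  names(maps) <- conds
  wm <- do.call(rbind, lapply(subjects, `[[`, "window_means"))
  freqs <- subjects[[1L]]$ali$freqs
  times <- subjects[[1L]]$ali$times
  cl <- cluster_test(maps$target_lateral, maps$distractor_lateral,
                     n_perm = n_perm, seed = seed, freqs = freqs,
                     times = times, ...)
  structure(list(window_means = wm, maps = maps, cluster = cl,
                 followup = ali_followup(wm),
                 behavior = behavioral_analysis(
                   lapply(subjects, `[[`, "trials")),
                 freqs = freqs, times = times, n_subjects = n_subjects),
            class = "ali_study")
}

#' @export
print.ali_study <- function(x, ...) {
  cat(sprintf("<ali_study> %d simulated subjects\n\n", x$n_subjects))
  cat("Group-mean window ALI:\n")
  print(round(colMeans(x$window_means), 4))
  cat("\n")
  print(x$cluster)
  cat("\n")
  print(x$followup)
  invisible(x)
}

#' Does any significant cluster overlap a band/window?
#'
#' @param cl a `cluster_test` with frequency/time axes.
#' @param band frequency interval (Hz).
#' @param window_ms time interval (epoch ms).
#' @return logical.
#' @export
cluster_overlaps_window <- function(cl, band = c(8, 13),
                                    window_ms = RETROCUE_ONSET_MS +
                                      c(700, 1300)) {
  stopifnot(inherits(cl, "cluster_test"))
  for (c in cl$clusters) {
    if (!isTRUE(c$significant)) next
    rc <- arrayInd(c$members, dim(cl$t_map))
    f <- cl$freqs[rc[, 1L]]; t <- cl$times[rc[, 2L]]
    if (any(f >= band[1L] & f <= band[2L] &
            t >= window_ms[1L] & t <= window_ms[2L]))
      return(TRUE)
  }
  FALSE
}
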