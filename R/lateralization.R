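# Alpha Lateralization Index: hemispheric contrast of posterior alpha power
# relative to the lateralized working-memory item.

#' Posterior electrode cluster pairs
#'
#' The left/right homologue pairs over which power is averaged before the
#' lateralization contrast: PO7/PO8, P7/P8, P5/P6, PO3/PO4.
#'
#' @return A list of length-2 character vectors `(left, right)`.
#' @export
default_cluster_pairs <- function() {
  list(c("PO7", "PO8"), c("P7", "P8"), c("P5", "P6"), c("PO3", "PO4"))
}

check_pairs <- function(pairs) {
  ok <- is.list(pairs) && length(pairs) > 0 &&
    all(vapply(pairs, length, integer(1)) == 2L)
  if (!ok) stop_fmt("`pairs` must be a list of (left, right) label pairs")
  sides_l <- channel_side(vapply(pairs, `[`, character(1), 1L))
  sides_r <- channel_side(vapply(pairs, `[`, character(1), 2L))
  if (any(sides_l != "left") || any(sides_r != "right"))
    stop_fmt("pairs must be (left-label, right-label) homologues")
  pairs
}

#' Side of the lateralized item
#'
#' The lateral sound retained in working memory after the pre-cue sits on the
#' pre-cued side; it is the *target* in target-lateral and neutral trials and
#' the *distractor* in distractor-lateral trials. Either way, ipsi/contra
#' assignment of electrodes is made relative to this side.
#'
#' @param trials a trial table (or subset of rows).
#' @return character vector, `"left"` or `"right"`, one per trial.
#' @export
lateral_side <- function(trials) {
  trials$precue_side
}

#' Trial-mean ipsilateral and contralateral power
#'
#' For every retained trial of the requested condition, the four left-
#' hemisphere cluster channels count as ipsilateral when the lateralized
#' item is on the left (contralateral otherwise), and conversely for the
#' right-hemisphere channels. Power is averaged over the four channels per
#' hemisphere, then across the condition's trials — the trial mean is taken
#' *before* the lateralization ratio downstream.
#'
#' @param tf a [tf_power] object whose trial dimension aligns with `trials`.
#' @param trials trial table with one row per trial of `tf`.
#' @param pairs electrode cluster pairs (default [default_cluster_pairs()]).
#' @param condition one of `"target_lateral"`, `"distractor_lateral"`,
#'   `"neutral"`.
#' @return list with `ipsi` and `contra` (frequency x time matrices),
#'   `freqs`, `times`, and `n_trials` used.
#' @export
ipsi_contra_power <- function(tf, trials, pairs = default_cluster_pairs(),
                              condition = c("target_lateral",
                                            "distractor_lateral", "neutral")) {
  stopifnot(inherits(tf, "tf_power"))
  condition <- match.arg(condition)
  check_pairs(pairs)
  if (dim(tf$power)[4L] != nrow(trials))
    stop_fmt("tf has %d trials but the table has %d rows",
             dim(tf$power)[4L], nrow(trials))
  left_ch <- vapply(pairs, `[`, character(1), 1L)
  right_ch <- vapply(pairs, `[`, character(1), 2L)
  li <- match(left_ch, tf$channels)
  ri <- match(right_ch, tf$channels)
  if (anyNA(li) || anyNA(ri))
    stop_fmt("tf_power lacks cluster channel(s): %s",
             paste(c(left_ch[is.na(li)], right_ch[is.na(ri)]), collapse = ", "))
  use <- which(retrocue_condition(trials$retrocue) == condition &
                 !trials$rejected)
  if (!length(use)) stop_fmt("no retained trials in condition '%s'", condition)
  side <- lateral_side(trials)[use]

  nf <- length(tf$freqs); nt <- length(tf$times)
  ipsi <- matrix(0, nf, nt); contra <- matrix(0, nf, nt)
  for (j in seq_along(use)) {
    tr <- use[j]
    lmean <- colMeans(matrix(tf$power[li, , , tr], length(li)))
    rmean <- colMeans(matrix(tf$power[ri, , , tr], length(ri)))
    dim(lmean) <- dim(rmean) <- c(nf, nt)
    if (side[j] == "left") {
      ipsi <- ipsi + lmean; contra <- contra + rmean
    } else {
      ipsi <- ipsi + rmean; contra <- contra + lmean
    }
  }
  list(ipsi = ipsi / length(use), contra = contra / length(use),
       freqs = tf$freqs, times = tf$times, n_trials = length(use))
}

#' Alpha Lateralization Index
#'
#' Elementwise `(ipsi - contra) / (ipsi + contra)`. Positive values indicate
#' a contralateral power decrease (prioritized processing of the lateralized
#' item), negative values a contralateral increase (its suppression). Where
#' total power is zero the index is defined as 0 (unreachable over a
#' pink-noise floor, but keeps the map total).
#'
#' @param ipsi,contra non-negative matrices of equal shape.
#' @return matrix of the same shape with values in `[-1, 1]`.
#' @export
compute_ali <- function(ipsi, contra) {
  if (!identical(dim(ipsi), dim(contra)))
    stop_fmt("ipsi and contra shapes differ")
  if (min(ipsi) < 0 || min(contra) < 0) stop_fmt("power must be non-negative")
  tot <- ipsi + contra
  ali <- ipsi - contra
  nz <- tot > 0
  ali[nz] <- ali[nz] / tot[nz]
  ali[!nz] <- 0
  ali
}

#' Window mean of a time-frequency map
#'
#' Unweighted mean over the grid points whose frequency lies in `band` and
#' whose time lies in `window_ms` (closed intervals on both axes).
#'
#' @param x frequency x time matrix.
#' @param freqs,times axis vectors matching `x`.
#' @param band frequency interval in Hz (default `c(8, 13)`).
#' @param window_ms time interval in epoch ms; the default is the
#'   700-1300 ms post-retro-cue window, i.e. 3700-4300 ms epoch time.
#' @return scalar mean.
#' @export
window_mean <- function(x, freqs, times, band = c(8, 13),
                        window_ms = RETROCUE_ONSET_MS + c(700, 1300)) {
  stopifnot(nrow(x) == length(freqs), ncol(x) == length(times))
  fi <- freqs >= band[1L] & freqs <= band[2L]
  ti <- times >= window_ms[1L] & times <= window_ms[2L]
  if (!any(fi) || !any(ti))
    stop_fmt("band/window [%g,%g] Hz x [%g,%g] ms does not intersect the grid",
             band[1L], band[2L], window_ms[1L], window_ms[2L])
  mean(x[fi, ti])
}

#' Per-condition ALI maps for one subject
#'
#' Convenience wrapper: computes trial-mean ipsi/contra power and the ALI
#' map for each condition, plus the alpha-band window mean.
#'
#' @inheritParams ipsi_contra_power
#' @param conditions conditions to compute (default: all three).
#' @param band,window_ms forwarded to [window_mean()].
#' @return list of class `ali_maps`: per condition a list with `ali`,
#'   `ipsi`, `contra`, `window_mean`, `n_trials`; plus `freqs`, `times`.
#' @export
subject_ali <- function(tf, trials, pairs = default_cluster_pairs(),
                        conditions = c("target_lateral", "distractor_lateral",
                                       "neutral"),
                        band = c(8, 13),
                        window_ms = RETROCUE_ONSET_MS + c(700, 1300)) {
  out <- list()
  for (cond in conditions) {
    pw <- ipsi_contra_power(tf, trials, pairs, cond)
    ali <- compute_ali(pw$ipsi, pw$contra)
    out[[cond]] <- list(ali = ali, ipsi = pw$ipsi, contra = pw$contra,
                        window_mean = window_mean(ali, pw$freqs, pw$times,
                                                  band, window_ms),
                        n_trials = pw$n_trials)
  }
  structure(c(out, list(freqs = tf$freqs, times = tf$times)),
            class = "ali_maps")
}
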