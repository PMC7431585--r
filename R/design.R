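#' Generate the retro-cue trial design
#'
#' Builds the full factorial trial list of the auditory retro-cue task. Each
#' of the four retro-cue tokens (`li`, `re`, `mi`, `bei`) occurs on exactly
#' 25% of trials, so target-lateral cues (`li` + `re`) make up 50% of trials.
#' Cued probes (requiring a YES response) occur on 50% of trials overall and
#' within every token; non-cued and new probes (NO response) each cover 25%
#' of trials overall. Neutral (`bei`) trials never carry a non-cued probe —
#' both items remain relevant — so the total non-cued count is spread over
#' the three selective tokens in a 2:1 ratio with new probes (largest-
#' remainder rounding in the fixed order li, re, mi keeps the overall
#' proportions exact whenever `n_trials` is divisible by 16). Pre-cue side is
#' forced by the cue for `li`/`re` and balanced within cells for `mi`/`bei`.
#' Trials are pseudo-randomly ordered (reproducibly from `seed`) and grouped
#' into blocks of 100.
#'
#' @param n_trials number of trials; must be divisible by 16 so that every
#'   cue-by-probe cell is exactly realizable (default 800).
#' @param seed integer seed for the reproducible trial order.
#' @return A trial table (see [validate_trial_table()]) with `response`
#'   `"none"`, `rt_ms` `NA` and `correct` `NA` until behavior is simulated.
#' @examples
#' d <- generate_design(16, seed = 1)
#' table(d$retrocue)
#' @export
generate_design <- function(n_trials = 800, seed = 1) {
  if (!is_count(n_trials) || n_trials %% 16L != 0L)
    stop_fmt("`n_trials` must be a positive multiple of 16 (got %s)",
             format(n_trials))
  n <- as.integer(n_trials)
  per_token <- n %/% 4L      # 25% per retro-cue token
  cued_per_token <- n %/% 8L # cued probes: 50% within every token

  # distribute the n/4 non-cued probes over li, re, mi (largest remainder)
  noncued_total <- n %/% 4L
  base <- noncued_total %/% 3L
  extra <- noncued_total %% 3L
  noncued <- c(li = base, re = base, mi = base) +
    c(li = 1L, re = 1L, mi = 1L) * (seq_len(3L) <= extra)

  rows <- list()
  for (tok in .retrocue_tokens) {
    nc <- if (tok == "bei") 0L else unname(noncued[tok])
    nn <- per_token - cued_per_token - nc
    probe <- c(rep("cued", cued_per_token), rep("noncued", nc),
               rep("new", nn))
    side <- if (tok == "li") rep("left", per_token)
            else if (tok == "re") rep("right", per_token)
            else unlist(lapply(c(cued_per_token, nc, nn), function(k)
              rep_len(c("left", "right"), k)), use.names = FALSE)
    rows[[tok]] <- data.frame(precue_side = side, retrocue = tok,
                              probe = probe, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  d <- with_seed(seed, d[sample.int(nrow(d)), , drop = FALSE])
  rownames(d) <- NULL
  d <- data.frame(trial_id = seq_len(n),
                  block = (seq_len(n) - 1L) %/% 100L + 1L,
                  d,
                  response = "none", rt_ms = NA_real_, correct = NA,
                  rejected = FALSE, stringsAsFactors = FALSE)
  validate_trial_table(d)
  d
}
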