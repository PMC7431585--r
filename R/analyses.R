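# The two scripted analyses: retro-cue / probe-type behavioral comparisons
# and the follow-up statistics on windowed ALI values. Both use the
# Benjamini-Yekutieli variant of the FDR correction (uncapped), the
# convention under which adjusted p-values can exceed 1.

VALID_RT_MIN_MS <- 200
VALID_RT_MAX_MS <- RESPONSE_WINDOW_MS + PROBE_DURATION_MS  # 2100 ms

# Per-subject condition summaries. Error trials are late (> valid window),
# premature (< 200 ms) or missing responses, plus wrong answers; RT means
# use correct, validly timed trials only.
subject_summaries <- function(trials) {
  validate_trial_table(trials)
  trials <- trials[!trials$rejected, , drop = FALSE]
  timed <- !is.na(trials$rt_ms) & trials$rt_ms >= VALID_RT_MIN_MS &
    trials$rt_ms <= VALID_RT_MAX_MS
  ok <- !is.na(trials$correct) & trials$correct & timed
  cond <- retrocue_condition(trials$retrocue)
  selective <- cond != "neutral"

  cell <- function(rows) {
    if (!sum(rows)) return(c(rt = NA_real_, acc = NA_real_))
    c(rt = mean(trials$rt_ms[rows & ok]),
      acc = mean(ok[rows]))
  }
  # analysis 1 cells exclude non-cued probes to keep conditions balanced
  not_nc <- trials$probe != "noncued"
  a1 <- rbind(selective = cell(selective & not_nc),
              neutral = cell(!selective))
  # analysis 2: probe types within selective trials only
  a2 <- rbind(cued = cell(selective & trials$probe == "cued"),
              noncued = cell(selective & trials$probe == "noncued"),
              new = cell(selective & trials$probe == "new"))
  list(a1 = a1, a2 = a2)
}

# Lilliefors-gated paired comparison: paired t when the difference scores
# look normal (p > gate), Wilcoxon signed-rank otherwise. A Bayes factor
# from the t statistic is attached either way.
gated_paired <- function(x, y, gate = 0.05, bf_scale = sqrt(2) / 2) {
  d <- x - y
  normal <- tryCatch(lilliefors(d)$p > gate, error = function(e) TRUE)
  res <- if (normal) paired_t(x, y, bf_scale = bf_scale)
         else wilcoxon_signed_rank(x, y)
  if (!normal) {
    res$effect_size <- hedges_g(x, y)
    res$effect_type <- "g"
    tt <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    res$bf <- bf_ttest(tt, length(d), bf_scale)
  }
  res
}

#' Behavioral retro-cue and probe-type analysis
#'
#' Reproduces the two behavioral analysis families on a list of per-subject
#' trial tables. Analysis 1 contrasts selective versus neutral retro-cues on
#' mean response time (correct trials only) and accuracy, excluding
#' non-cued-probe trials, which cannot occur under a neutral cue. Analysis 2
#' contrasts the three probe types within selective trials: a one-way
#' repeated-measures ANOVA for response times and Friedman's ANOVA for
#' accuracy, followed by pairwise post-hoc tests. Paired contrasts take the
#' parametric route only when the difference scores pass a Lilliefors gate.
#' For each measure, the two family-level p-values (cue-type test and
#' probe-type test) are FDR-corrected together; post-hoc p-values are
#' corrected within their own family per measure. Hedges g and a JZS Bayes
#' factor accompany every pairwise test. Adjusted p-values are uncapped and
#' can exceed 1.
#'
#' @param trial_tables list of >= 2 per-subject trial tables.
#' @param gate Lilliefors alpha for the parametric gate (default 0.05).
#' @param fdr_method FDR variant (default `"by"`; see [fdr_adjust()]).
#' @return list of class `behavior_analysis` with elements `main` and
#'   `posthoc` (data.frames of test results) and `summaries` (per-subject
#'   condition means).
#' @export
behavioral_analysis <- function(trial_tables, gate = 0.05,
                                fdr_method = "by") {
  if (!is.list(trial_tables) || length(trial_tables) < 2L)
    stop_fmt("need a list of at least 2 subjects' trial tables")
  sums <- lapply(trial_tables, subject_summaries)
  pull <- function(part, row, col)
    vapply(sums, function(s) s[[part]][row, col], numeric(1))
  cells <- list(
    rt_sel = pull("a1", "selective", "rt"),
    rt_neu = pull("a1", "neutral", "rt"),
    acc_sel = pull("a1", "selective", "acc"),
    acc_neu = pull("a1", "neutral", "acc"),
    rt_cued = pull("a2", "cued", "rt"),
    rt_noncued = pull("a2", "noncued", "rt"),
    rt_new = pull("a2", "new", "rt"),
    acc_cued = pull("a2", "cued", "acc"),
    acc_noncued = pull("a2", "noncued", "acc"),
    acc_new = pull("a2", "new", "acc"))
  bad <- names(cells)[vapply(cells, anyNA, logical(1))]
  if (length(bad))
    stop_fmt("subject(s) lack trials in required cell(s): %s",
             paste(bad, collapse = ", "))

  main <- list(
    rt_cue_type = gated_paired(cells$rt_sel, cells$rt_neu, gate),
    rt_probe_type = rm_anova_1way(cbind(cued = cells$rt_cued,
                                        noncued = cells$rt_noncued,
                                        new = cells$rt_new)),
    acc_cue_type = gated_paired(cells$acc_sel, cells$acc_neu, gate),
    acc_probe_type = friedman(cbind(cued = cells$acc_cued,
                                    noncued = cells$acc_noncued,
                                    new = cells$acc_new)))
  # per measure, the two analyses form one FDR family
  fam <- c("rt", "rt", "acc", "acc")
  adj <- fdr_adjust(vapply(main, `[[`, numeric(1), "p"), fam, fdr_method)
  for (i in seq_along(main)) main[[i]]$p_adj <- adj[i]

  pairs <- list(c("noncued", "new"), c("cued", "new"), c("cued", "noncued"))
  posthoc <- list()
  for (measure in c("rt", "acc")) {
    for (pr in pairs) {
      nm <- sprintf("%s_%s_vs_%s", measure, pr[1L], pr[2L])
      posthoc[[nm]] <- gated_paired(cells[[paste0(measure, "_", pr[1L])]],
                                    cells[[paste0(measure, "_", pr[2L])]],
                                    gate)
    }
  }
  fam_ph <- rep(c("rt", "acc"), each = 3L)
  adj_ph <- fdr_adjust(vapply(posthoc, `[[`, numeric(1), "p"), fam_ph,
                       fdr_method)
  for (i in seq_along(posthoc)) posthoc[[i]]$p_adj <- adj_ph[i]

  structure(list(main = tests_to_frame(main),
                 posthoc = tests_to_frame(posthoc),
                 summaries = cells),
            class = "behavior_analysis")
}

tests_to_frame <- function(tests) {
  data.frame(
    test = names(tests),
    method = vapply(tests, `[[`, character(1), "method"),
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    df = vapply(tests, function(t) paste(format(t$df, digits = 4),
                                         collapse = ","), character(1)),
    p = vapply(tests, `[[`, numeric(1), "p"),
    p_adj = vapply(tests, `[[`, numeric(1), "p_adj"),
    effect_size = vapply(tests, function(t) t$effect_size %||% NA_real_,
                         numeric(1)),
    bf = vapply(tests, function(t) as.numeric(t$bf %||% NA_real_),
                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.behavior_analysis <- function(x, ...) {
  cat("Behavioral analysis (uncapped FDR-adjusted p-values)\n\nMain tests:\n")
  print(x$main, digits = 4)
  cat("\nPost-hoc probe-type contrasts:\n")
  print(x$posthoc, digits = 4)
  invisible(x)
}

#' Follow-up statistics on windowed ALI values
#'
#' Given per-subject window-mean ALI values for the three retro-cue
#' conditions, runs the five follow-up comparisons: paired t-tests of
#' neutral against target-lateral and against distractor-lateral, and
#' one-sample t-tests of each condition against zero. All five p-values
#' form a single FDR family (uncapped adjustment); Hedges g / g1 and JZS
#' Bayes factors are attached.
#'
#' @param window_means numeric subject x condition matrix with columns
#'   `target_lateral`, `distractor_lateral`, `neutral`.
#' @param fdr_method FDR variant (default `"by"`).
#' @return list of class `ali_followup` with a `tests` data.frame.
#' @export
ali_followup <- function(window_means, fdr_method = "by") {
  wm <- as.matrix(window_means)
  need <- c("target_lateral", "distractor_lateral", "neutral")
  if (!all(need %in% colnames(wm)))
    stop_fmt("window_means needs columns: %s", paste(need, collapse = ", "))
  if (nrow(wm) < 2L) stop_fmt("need at least 2 subjects")
  tests <- list(
    neutral_vs_target = paired_t(wm[, "neutral"], wm[, "target_lateral"]),
    neutral_vs_distractor = paired_t(wm[, "neutral"],
                                     wm[, "distractor_lateral"]),
    target_vs_zero = one_sample_t(wm[, "target_lateral"]),
    distractor_vs_zero = one_sample_t(wm[, "distractor_lateral"]),
    neutral_vs_zero = one_sample_t(wm[, "neutral"]))
  adj <- fdr_adjust(vapply(tests, `[[`, numeric(1), "p"),
                    method = fdr_method)
  for (i in seq_along(tests)) tests[[i]]$p_adj <- adj[i]
  structure(list(tests = tests_to_frame(tests), n = nrow(wm)),
            class = "ali_followup")
}

#' @export
print.ali_followup <- function(x, ...) {
  cat(sprintf("ALI follow-up tests (n = %d; one FDR family of %d)\n\n",
              x$n, nrow(x$tests)))
  print(x$tests, digits = 4)
  invisible(x)
}
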