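# Statistical toolbox: t-tests with Hedges g effect sizes, Wilcoxon
# signed-rank, one-way repeated-measures ANOVA with Mauchly's sphericity
# test and Greenhouse-Geisser correction, Friedman's ANOVA, uncapped FDR
# correction (Benjamini-Hochberg and Benjamini-Yekutieli variants), JZS
# Bayes factors, and a Lilliefors normality gate.

#' Container for a single test result
#'
#' @param method short method label.
#' @param statistic test statistic.
#' @param df degrees of freedom (scalar or length-2 for F).
#' @param p two-tailed p-value.
#' @param effect_size effect size value (may be `NA`).
#' @param effect_type label of the effect size (`"g"`, `"g1"`, `"etap2"`, ...).
#' @param bf JZS Bayes factor BF10 (may be `NA`).
#' @param n sample size.
#' @param extra named list of method-specific fields.
#' @return object of class `wm_test`.
#' @export
wm_test <- function(method, statistic, df, p, effect_size = NA_real_,
                    effect_type = NA_character_, bf = NA_real_, n = NA_integer_,
                    extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df, p = p,
                   p_adj = NA_real_, effect_size = effect_size,
                   effect_type = effect_type, bf = bf, n = n,
                   tails = "two"), extra),
            class = "wm_test")
}

#' @export
print.wm_test <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g", x$method,
              x$statistic, dfs, x$p))
  if (!is.na(x$p_adj)) cat(sprintf(", p_adj = %.4g", x$p_adj))
  if (!is.na(x$effect_size))
    cat(sprintf(", %s = %.3g", x$effect_type, x$effect_size))
  if (!is.na(x$bf)) cat(sprintf(", BF10 = %.4g", x$bf))
  cat("\n")
  invisible(x)
}

#' Hedges g effect sizes
#'
#' Standardized mean difference with the small-sample bias correction
#' `J = 1 - 3 / (4 df - 1)`, `df = n - 1`. For paired designs the default
#' standardizer is the SD of the difference scores
#' (`method = "differences"`); `method = "average"` divides by the mean of
#' the two condition SDs instead. `hedges_g1()` is the one-sample analogue
#' against `mu0`.
#'
#' @param x,y paired samples.
#' @param method paired standardizer, `"differences"` (default) or
#'   `"average"`.
#' @param mu0 null value for the one-sample version.
#' @return numeric scalar.
#' @export
hedges_g <- function(x, y, method = c("differences", "average")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- length(d)
  J <- 1 - 3 / (4 * (n - 1) - 1)
  sdev <- switch(method,
                 differences = stats::sd(d),
                 average = (stats::sd(x) + stats::sd(y)) / 2)
  if (sdev == 0) return(if (mean(d) == 0) 0 else NaN)
  J * mean(d) / sdev
}

#' @rdname hedges_g
#' @export
hedges_g1 <- function(x, mu0 = 0) {
  n <- length(x)
  J <- 1 - 3 / (4 * (n - 1) - 1)
  sdev <- stats::sd(x)
  if (sdev == 0) return(if (mean(x) == mu0) 0 else NaN)
  J * (mean(x) - mu0) / sdev
}

#' Paired and one-sample t-tests with effect size and Bayes factor
#'
#' Two-tailed t-tests returning a [wm_test] with Hedges g (paired) or g1
#' (one-sample) and the JZS Bayes factor. A sample whose values are all
#' identical to the null (zero variance, zero mean difference) yields
#' t = 0, p = 1, g = 0; zero variance around a nonzero mean is an error.
#'
#' @param x,y numeric vectors (equal length, n >= 2).
#' @param mu0 one-sample null value.
#' @param g_method paired-g standardizer, see [hedges_g()].
#' @param bf_scale Cauchy prior scale for the Bayes factor.
#' @return a [wm_test].
#' @export
paired_t <- function(x, y, g_method = "differences", bf_scale = sqrt(2) / 2) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop_fmt("need n >= 2 pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m != 0) stop_fmt("zero variance of differences with nonzero mean")
    return(wm_test("paired t", 0, n - 1L, 1, 0, "g", bf_ttest(0, n, bf_scale),
                   n))
  }
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1L)
  wm_test("paired t", t, n - 1L, p, hedges_g(x, y, g_method), "g",
          bf_ttest(t, n, bf_scale), n)
}

#' @rdname paired_t
#' @export
one_sample_t <- function(x, mu0 = 0, bf_scale = sqrt(2) / 2) {
  n <- length(x)
  if (n < 2L) stop_fmt("need n >= 2")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) {
    if (m != mu0) stop_fmt("zero variance with mean != mu0")
    return(wm_test("one-sample t", 0, n - 1L, 1, 0, "g1",
                   bf_ttest(0, n, bf_scale), n))
  }
  t <- (m - mu0) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1L)
  wm_test("one-sample t", t, n - 1L, p, hedges_g1(x, mu0), "g1",
          bf_ttest(t, n, bf_scale), n)
}

#' Wilcoxon signed-rank test
#'
#' Paired (or one-sample, `y = NULL`) signed-rank test, two-tailed. Zero
#' differences are dropped. With n <= 25 untied differences the exact
#' signed-rank distribution is used; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y numeric vectors.
#' @return a [wm_test] whose statistic `V` is the positive-rank sum; the
#'   `extra` field `exact` records which route was taken.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L) stop_fmt("need at least 2 nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  exact <- n <= 25L && !ties
  if (exact) {
    if (V > n * (n + 1) / 4) {
      p <- 2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
    } else {
      p <- 2 * stats::psignrank(V, n)
    }
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  wm_test("Wilcoxon signed-rank", V, NA_real_, p,
          n = n, extra = list(exact = exact))
}

# Orthonormal polynomial-free contrast matrix (k x (k-1)) spanning the
# within-subject differences.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  qr.Q(qr(C))
}

#' One-way repeated-measures ANOVA
#'
#' F-test of the level effect with `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom and partial eta squared. Mauchly's test for sphericity is run on
#' the covariance of the orthonormalized within-subject contrasts; when it
#' rejects at `sphericity_alpha`, the Greenhouse-Geisser estimate of epsilon
#' multiplies both degrees of freedom before the p-value is computed.
#' Epsilon and Mauchly's result are always reported.
#'
#' @param data numeric subject x level matrix, complete (no missing cells).
#' @param sphericity_alpha level of the Mauchly gate (default 0.05).
#' @return a [wm_test] with extra fields `mauchly_w`, `mauchly_p`,
#'   `epsilon`, `gg_applied`, `df_corrected`.
#' @export
rm_anova_1way <- function(data, sphericity_alpha = 0.05) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (k < 2L) stop_fmt("need at least 2 levels")
  if (n < 3L) stop_fmt("need at least 3 subjects")
  if (anyNA(data)) stop_fmt("missing cells are not supported")
  grand <- mean(data)
  ss_effect <- n * sum((colMeans(data) - grand)^2)
  ss_subject <- k * sum((rowMeans(data) - grand)^2)
  ss_total <- sum((data - grand)^2)
  ss_error <- ss_total - ss_effect - ss_subject
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_effect <- ss_effect / df1
  ms_error <- ss_error / df2
  F <- if (ms_error > 0) ms_effect / ms_error else ifelse(ms_effect > 0, Inf, 0)
  etap2 <- if (ss_effect + ss_error > 0) ss_effect / (ss_effect + ss_error)
           else 0

  C <- orthonormal_contrasts(k)
  S <- stats::cov(data)
  Tm <- t(C) %*% S %*% C
  # Greenhouse-Geisser epsilon from the contrast covariance
  eps <- sum(diag(Tm))^2 / ((k - 1) * sum(Tm^2))
  # Mauchly's W and its chi-square approximation
  if (k == 2L) {
    W <- 1; mauchly_p <- 1
  } else {
    detT <- det(Tm)
    W <- if (detT <= 0) 0 else detT / (sum(diag(Tm)) / (k - 1))^(k - 1)
    dfM <- k * (k - 1) / 2 - 1
    if (W <= 0) {
      mauchly_p <- 0
    } else {
      fac <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
      chi2 <- -(n - 1) * fac * log(W)
      mauchly_p <- stats::pchisq(chi2, dfM, lower.tail = FALSE)
    }
  }
  gg <- mauchly_p < sphericity_alpha
  df1_use <- if (gg) df1 * eps else df1
  df2_use <- if (gg) df2 * eps else df2
  p <- stats::pf(F, df1_use, df2_use, lower.tail = FALSE)
  wm_test("rm-ANOVA", F, c(df1_use, df2_use), p, etap2, "etap2", n = n,
          extra = list(mauchly_w = W, mauchly_p = mauchly_p, epsilon = eps,
                       gg_applied = gg, df_uncorrected = c(df1, df2)))
}

#' Friedman's rank ANOVA
#'
#' Nonparametric one-way repeated-measures test on ranks (mid-ranks for
#' ties), chi-squared with k - 1 degrees of freedom.
#'
#' @param data numeric subject x level matrix.
#' @return a [wm_test].
#' @export
friedman <- function(data) {
  data <- as.matrix(data)
  if (ncol(data) < 2L || nrow(data) < 2L)
    stop_fmt("need at least 2 levels and 2 subjects")
  ft <- stats::friedman.test(data)
  wm_test("Friedman", unname(ft$statistic), unname(ft$parameter),
          ft$p.value, n = nrow(data))
}

#' Uncapped FDR correction
#'
#' Step-up false-discovery-rate adjustment within each family:
#' `p_(i) * m * c(m) / i` with monotonicity enforced from the largest rank
#' down, where `c(m) = 1` for the Benjamini-Hochberg variant and
#' `c(m) = sum(1/i)` for the Benjamini-Yekutieli variant (valid under
#' arbitrary dependence). Values are deliberately **not** capped at 1: under
#' the BY variant an adjusted p-value can exceed 1, and such values are
#' reported as-is.
#'
#' @param p vector of p-values in (0, 1].
#' @param families optional grouping vector; correction is applied within
#'   each family separately.
#' @param method `"bh"` (default) or `"by"`.
#' @return adjusted p-values in the input order (`>= p` elementwise).
#' @export
fdr_adjust <- function(p, families = NULL, method = c("bh", "by")) {
  method <- match.arg(method)
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop_fmt("p-values must lie in (0, 1]")
  if (is.null(families)) families <- rep(1L, length(p))
  stopifnot(length(families) == length(p))
  out <- rep(NA_real_, length(p))
  for (f in unique(families)) {
    sel <- which(families == f & !is.na(p))
    m <- length(sel)
    if (!m) next
    ps <- p[sel]
    o <- order(ps)
    cm <- if (method == "by") sum(1 / seq_len(m)) else 1
    wtd <- ps[o] * m * cm / seq_len(m)
    adj <- rev(cummin(rev(wtd)))
    out[sel[o]] <- adj
  }
  out
}

#' @rdname fdr_adjust
#' @export
fdr_bh <- function(p, families = NULL) fdr_adjust(p, families, "bh")

#' JZS Bayes factor for one-sample / paired t designs
#'
#' BF10 under the default Jeffreys-Zellner-Siow setup: a Cauchy prior with
#' scale `scale` on the standardized effect size against the point null.
#' Computed as the ratio of the marginal likelihood of the observed t
#' statistic — the noncentral t density averaged over the prior by adaptive
#' quadrature — to the central t density.
#'
#' @param t observed t statistic.
#' @param n sample size (pairs for a paired design).
#' @param scale Cauchy prior scale (default `sqrt(2)/2`).
#' @return positive scalar BF10.
#' @export
bf_ttest <- function(t, n, scale = sqrt(2) / 2) {
  if (n < 2) stop_fmt("need n >= 2")
  nu <- n - 1
  like <- function(delta)
    stats::dt(t, nu, ncp = sqrt(n) * delta) * stats::dcauchy(delta, 0, scale)
  # dt(ncp = ...) emits a benign precision notice; accuracy is checked
  # against an independent quadrature of the g-mixture representation.
  num <- tryCatch(
    suppressWarnings(stats::integrate(like, -Inf, Inf, rel.tol = 1e-9,
                                      abs.tol = 0)$value),
    error = function(e) stop_fmt("Bayes factor integration failed: %s",
                                 conditionMessage(e)))
  num / stats::dt(t, nu)
}

# ---- Lilliefors ------------------------------------------------------------

.lillie_cache <- new.env(parent = emptyenv())

lillie_stat <- function(x) {
  n <- length(x)
  z <- (sort(x) - mean(x)) / stats::sd(x)
  Phi <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - Phi, Phi - (seq_len(n) - 1) / n))
}

#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' SD estimated from the sample. The p-value comes from a Monte-Carlo null
#' table (`n_sim` standard-normal samples of the same n, computed once per n
#' with a fixed internal seed and cached), so the parametric/non-parametric
#' gate is deterministic per configuration.
#'
#' @param x numeric vector, n >= 4.
#' @param n_sim null-table size (default 10000).
#' @return a [wm_test] with the KS statistic and Monte-Carlo p.
#' @export
lilliefors <- function(x, n_sim = 10000L) {
  n <- length(x)
  if (n < 4L) stop_fmt("need n >= 4")
  if (stats::sd(x) == 0) stop_fmt("sample is constant")
  D <- lillie_stat(x)
  key <- sprintf("n%d_B%d", n, n_sim)
  if (is.null(.lillie_cache[[key]])) {
    .lillie_cache[[key]] <- with_seed(1907L + n, {
      vapply(seq_len(n_sim), function(i) lillie_stat(stats::rnorm(n)),
             numeric(1))
    })
  }
  null <- .lillie_cache[[key]]
  p <- (1 + sum(null >= D)) / (n_sim + 1)
  wm_test("Lilliefors", D, NA_real_, p, n = n)
}
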