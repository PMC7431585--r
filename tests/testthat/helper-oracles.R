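# Independent oracles used to verify the package's own implementations.
# These deliberately use different algorithms from the code under test.

# Exhaustive flood-fill connected components (4-neighborhood) on a logical
# mask, optionally split by the sign of `s`. Returns a canonical set-of-sets
# representation: a sorted list of sorted member-index vectors.
flood_fill_components <- function(mask, s = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || seen[i, j]) next
      stack <- list(c(i, j))
      seen[i, j] <- TRUE
      members <- integer(0)
      while (length(stack)) {
        cell <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        members <- c(members, (cell[2] - 1L) * nr + cell[1])
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ni <- cell[1] + d[1]; nj <- cell[2] + d[2]
          if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
          if (!mask[ni, nj] || seen[ni, nj]) next
          if (!is.null(s) && s[ni, nj] != s[cell[1], cell[2]]) next
          seen[ni, nj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
      comps[[length(comps) + 1L]] <- sort(members)
    }
  }
  canonical_sets(comps)
}

canonical_sets <- function(sets) {
  sets <- lapply(sets, function(s) as.integer(sort(s)))
  sets[order(vapply(sets, `[`, integer(1), 1L))]
}

clusters_as_sets <- function(clusters) {
  canonical_sets(lapply(clusters, `[[`, "members"))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (doubling rule, as in the implementation under test).
wilcoxon_exact_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.vector(signs %*% r)
  lo <- mean(V_all <= V_obs)
  hi <- mean(V_all >= V_obs)
  min(1, 2 * min(lo, hi))
}

# JZS Bayes factor by quadrature of the Rouder g-mixture representation —
# an algebraically different route from the noncentral-t marginal used in
# the package.
bf_rouder_oracle <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  num <- stats::integrate(function(g)
    (1 + n * g * r^2)^(-0.5) *
      (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g)),
    0, Inf, rel.tol = 1e-10)$value
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# Reference uncapped step-up FDR: adj_(i) = min_{j >= i} p_(j) * m * c / j,
# computed by direct minimization rather than cummin.
fdr_stepup_oracle <- function(p, cm = 1) {
  m <- length(p)
  o <- order(p)
  wtd <- p[o] * m * cm / seq_len(m)
  adj <- vapply(seq_len(m), function(i) min(wtd[i:m]), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Small epoch set filled with white noise; posterior cluster channels first.
make_noise_epochs <- function(n_ch = 8, n_samples = 500, n_trials = 4,
                              srate = 500, seed = 1,
                              channels = c("PO7", "PO8", "P7", "P8",
                                           "P5", "P6", "PO3", "PO4")) {
  set.seed(seed)
  eeg_epochs(array(rnorm(n_ch * n_samples * n_trials),
                   c(n_ch, n_samples, n_trials)),
             srate, -1000, channels[seq_len(n_ch)])
}
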