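# Paired time-by-frequency cluster-based permutation test. Pointwise paired
# t-tests threshold the map; supra-threshold points form 4-connected,
# sign-uniform clusters; cluster sizes are referred to a permutation null of
# maximum cluster sizes obtained by randomly re-assigning condition labels
# within subjects (equivalently, sign-flipping the paired differences).

as_subject_matrix <- function(a) {
  d <- dim(a)
  if (is.null(d) || length(d) != 3L)
    stop_fmt("expected a subject x frequency x time array")
  list(m = matrix(a, d[1L], d[2L] * d[3L]), nf = d[2L], nt = d[3L])
}

#' Pointwise paired t-maps
#'
#' Paired t-test of `a` against `b` at every time-frequency point, two-tailed
#' with n-1 degrees of freedom. Points with zero difference variance have an
#' undefined t; their p is set to 1 with a warning.
#'
#' @param a,b subject x frequency x time arrays of equal shape.
#' @return list with `t_map` and `p_map` (frequency x time), `df`.
#' @export
pointwise_paired_t <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_fmt("`a` and `b` shapes differ")
  A <- as_subject_matrix(a)
  n <- dim(a)[1L]
  if (n < 2L) stop_fmt("need at least 2 subjects")
  d <- A$m - matrix(b, n, A$nf * A$nt)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1L)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  degenerate <- v == 0
  if (any(degenerate)) {
    t[degenerate & m == 0] <- 0
    warning(sprintf("%d grid point(s) with zero difference variance; p set to 1",
                    sum(degenerate)), call. = FALSE)
  }
  p <- 2 * stats::pt(-abs(t), n - 1L)
  p[degenerate] <- 1
  t[!is.finite(t)] <- 0
  list(t_map = matrix(t, A$nf, A$nt), p_map = matrix(p, A$nf, A$nt),
       df = n - 1L)
}

# Connected components (4-neighborhood) of the grid cells listed in `idx`
# (linear indices into an nr x nc matrix). Returns an integer component
# label per element of `idx`. Union-find with path halving.
label_components <- function(idx, nr, nc) {
  k <- length(idx)
  if (k == 0L) return(integer(0))
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(k)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  link <- function(ii, jj) {
    ri <- find(ii); rj <- find(jj)
    if (ri != rj) parent[ri] <<- rj
  }
  for (e in seq_len(k)) {
    if (row[e] > 1L && pos[idx[e] - 1L] > 0L) link(e, pos[idx[e] - 1L])
    if (col[e] > 1L && pos[idx[e] - nr] > 0L) link(e, pos[idx[e] - nr])
  }
  vapply(seq_len(k), find, integer(1))
}

#' Find supra-threshold clusters
#'
#' Partitions grid points with `p < alpha` into maximal 4-connected
#' components (adjacent along the time OR frequency axis, no diagonals). By
#' default clusters are additionally required to have uniform t-sign:
#' physically, a coherent effect does not flip direction within a cluster.
#'
#' @param p_map,t_map frequency x time matrices of equal shape.
#' @param alpha pointwise threshold (default 0.05).
#' @param same_sign require uniform t-sign within a cluster (default TRUE).
#' @return list of clusters, each a list with `members` (linear indices into
#'   the map), `size`, and `sign` (+1/-1, or 0 when `same_sign = FALSE` and
#'   signs are mixed). Empty list when nothing is supra-threshold.
#' @export
find_clusters <- function(p_map, t_map, alpha = 0.05, same_sign = TRUE) {
  if (!identical(dim(p_map), dim(t_map))) stop_fmt("map shapes differ")
  nr <- nrow(p_map); nc <- ncol(p_map)
  out <- list()
  groups <- if (same_sign) {
    list(which(p_map < alpha & t_map > 0), which(p_map < alpha & t_map < 0))
  } else {
    list(which(p_map < alpha))
  }
  for (idx in groups) {
    if (!length(idx)) next
    lab <- label_components(idx, nr, nc)
    for (g in unique(lab)) {
      members <- idx[lab == g]
      signs <- unique(sign(t_map[members]))
      out[[length(out) + 1L]] <-
        list(members = sort(members), size = length(members),
             sign = if (length(signs) == 1L) signs else 0)
    }
  }
  out[order(-vapply(out, `[[`, numeric(1), "size"))]
}

# Shared permutation engine. Paired design: each subject's condition labels
# are independently swapped or kept with probability 1/2, which equals
# multiplying that subject's difference map by -1. The t statistic of the
# flipped sample needs only the flipped mean, because sum(d^2) is invariant
# under sign flips. Permutation sign matrices are generated row by row so a
# longer run with the same seed extends a shorter one.
perm_max_sizes <- function(d, nf, nt, n_perm, alpha, same_sign, seed,
                          chunk = 250L) {
  n <- nrow(d)
  ss <- colSums(d^2)
  tcrit <- stats::qt(1 - alpha / 2, n - 1L)
  max_sizes <- integer(n_perm)
  with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n,
                  byrow = TRUE)
      M <- S %*% d / n
      V <- sweep(-(n * M^2), 2L, ss, "+") / (n - 1L)
      V[V <= 0] <- Inf
      Tm <- M / sqrt(V / n)
      supra <- abs(Tm) > tcrit
      for (b in seq_len(nb)) {
        idx <- which(supra[b, ])
        if (!length(idx)) next
        sz <- 0L
        groups <- if (same_sign)
          list(idx[Tm[b, idx] > 0], idx[Tm[b, idx] < 0]) else list(idx)
        for (g in groups) {
          if (!length(g)) next
          lab <- label_components(g, nf, nt)
          sz <- max(sz, max(tabulate(lab)))
        }
        max_sizes[done + b] <- sz
      }
      done <- done + nb
    }
  })
  max_sizes
}

#' Permutation null distribution of maximum cluster sizes
#'
#' For each iteration, every subject's pair of condition maps is
#' independently swapped or kept (probability 1/2, preserving the paired
#' design), the pointwise paired t-map and its supra-threshold clusters are
#' recomputed, and the size of the largest cluster (0 if none) is recorded.
#' Reproducible from `seed`; running more iterations with the same seed
#' extends the shorter run.
#'
#' @inheritParams pointwise_paired_t
#' @param n_perm number of permutations.
#' @param alpha pointwise threshold (default 0.05).
#' @param same_sign require sign-uniform clusters (default TRUE).
#' @param seed RNG seed.
#' @return integer vector of length `n_perm`.
#' @export
permutation_null <- function(a, b, n_perm = 1000, alpha = 0.05,
                             same_sign = TRUE, seed = 1) {
  if (!identical(dim(a), dim(b))) stop_fmt("`a` and `b` shapes differ")
  if (!is_count(n_perm)) stop_fmt("`n_perm` must be a positive integer")
  A <- as_subject_matrix(a)
  d <- A$m - matrix(b, dim(a)[1L], A$nf * A$nt)
  perm_max_sizes(d, A$nf, A$nt, n_perm, alpha, same_sign, seed)
}

# Empirical percentile cutoff: smallest observed null value whose rank
# reaches the percentile (ties included).
null_cutoff <- function(null_sizes, percentile) {
  sort(null_sizes)[ceiling(percentile * length(null_sizes))]
}

#' Cluster-based permutation test between two paired condition maps
#'
#' Runs the pointwise paired t-test, extracts observed supra-threshold
#' clusters, builds the permutation null of maximum cluster sizes, and flags
#' as significant every observed cluster strictly larger than the
#' `percentile` cutoff of the null (ties in the null count toward the
#' cutoff; a cluster exactly at the cutoff is not significant).
#'
#' @inheritParams permutation_null
#' @param percentile null-distribution percentile used as cutoff
#'   (default 0.95).
#' @param freqs,times optional axis vectors stored for reporting/plots.
#' @return Object of class `cluster_test`: `t_map`, `p_map`, `df`,
#'   `clusters` (each with `members`, `size`, `sign`, `significant`),
#'   `null_max_sizes`, `cutoff`, `alpha`, `percentile`, `n_perm`, `freqs`,
#'   `times`.
#' @export
cluster_test <- function(a, b, n_perm = 1000, alpha = 0.05,
                         percentile = 0.95, same_sign = TRUE, seed = 1,
                         freqs = NULL, times = NULL) {
  pt_res <- pointwise_paired_t(a, b)
  clusters <- find_clusters(pt_res$p_map, pt_res$t_map, alpha, same_sign)
  null_sizes <- permutation_null(a, b, n_perm, alpha, same_sign, seed)
  cutoff <- null_cutoff(null_sizes, percentile)
  for (i in seq_along(clusters))
    clusters[[i]]$significant <- clusters[[i]]$size > cutoff
  structure(list(t_map = pt_res$t_map, p_map = pt_res$p_map, df = pt_res$df,
                 clusters = clusters, null_max_sizes = null_sizes,
                 cutoff = cutoff, alpha = alpha, percentile = percentile,
                 n_perm = n_perm,
                 freqs = freqs %||% seq_len(nrow(pt_res$t_map)),
                 times = times %||% seq_len(ncol(pt_res$t_map))),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d x %d grid, df = %d, %d permutations\n",
              nrow(x$t_map), ncol(x$t_map), x$df, x$n_perm))
  cat(sprintf("  pointwise alpha %g; null %gth percentile cutoff: %d points\n",
              x$alpha, 100 * x$percentile, x$cutoff))
  if (!length(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    sig <- vapply(x$clusters, `[[`, logical(1), "significant")
    cat(sprintf("  %d cluster(s), %d significant; largest = %d points (sign %+d)\n",
                length(x$clusters), sum(sig), x$clusters[[1L]]$size,
                x$clusters[[1L]]$sign))
  }
  invisible(x)
}

#' @export
summary.cluster_test <- function(object, ...) {
  cl <- object$clusters
  data.frame(
    size = vapply(cl, `[[`, numeric(1), "size"),
    sign = vapply(cl, `[[`, numeric(1), "sign"),
    significant = vapply(cl, `[[`, logical(1), "significant"))
}

#' Plot a cluster test t-map with significant clusters outlined
#'
#' @param x a `cluster_test` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.cluster_test <- function(x, ...) {
  graphics::image(x$times, x$freqs, t(x$t_map),
                  xlab = "time (ms)", ylab = "frequency (Hz)",
                  main = "paired t-map", ...)
  for (cl in x$clusters) {
    if (!isTRUE(cl$significant)) next
    rc <- arrayInd(cl$members, dim(x$t_map))
    graphics::points(x$times[rc[, 2L]], x$freqs[rc[, 1L]], pch = 0,
                     cex = 0.6)
  }
  invisible(x)
}
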