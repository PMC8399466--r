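# Shared machinery for cluster-based permutation tests on time-course grids.
#
# All tests reduce to the same scheme: a pointwise (possibly weighted)
# one-sample t statistic on a 1-ms grid, clusters = maximal contiguous runs
# where |t| exceeds the two-tailed alpha quantile of t(N-1), cluster
# strength = sum of |t| over the run, and a sign-flipping permutation null
# of the maximum cluster strength. The weighted statistic uses weights
# normalized to sum 1 at each grid point with an effective-N correction:
#   m  = sum(u * v),  u = w / sum(w)
#   s2 = sum(u * (v - m)^2) / (1 - sum(u^2))
#   t  = m / sqrt(s2 * sum(u^2))        (df = N - 1)
# With uniform weights this is exactly the ordinary one-sample t.

# Stack a list of smoothed_series (common grid) into value/weight matrices,
# restricted to the analysis window. Grid points with zero value get zero
# weight so they contribute nothing.
series_matrix <- function(series, window_ms = NULL) {
  grid <- series[[1]]$grid_ms
  for (s in series) {
    if (!identical(s$grid_ms, grid)) stop_named("grid_mismatch", "series grids differ")
  }
  keep <- if (is.null(window_ms)) rep(TRUE, length(grid)) else {
    grid >= window_ms[1] & grid <= window_ms[2]
  }
  V <- do.call(rbind, lapply(series, function(s) s$value[keep]))
  W <- do.call(rbind, lapply(series, function(s) s$weight[keep]))
  W[is.na(V)] <- 0
  V[is.na(V)] <- 0
  list(V = V, W = W, grid = grid[keep])
}

# Pointwise weighted one-sample t for one sign assignment (observed: all +1).
# Returns t (0 where undefined), plus the per-point pieces for CIs.
wt_stats <- function(V, W) {
  N <- nrow(V)
  cs <- colSums(W)
  ok <- cs > 0
  U <- sweep(W, 2, ifelse(ok, cs, 1), "/")
  m <- colSums(U * V)
  k2 <- colSums(U^2)
  ss <- colSums(U * sweep(V, 2, m, "-")^2)
  denom <- pmax(1 - k2, .Machine$double.eps)
  s2 <- ss / denom
  se <- sqrt(s2 * k2)
  t <- ifelse(ok & se > 0, m / se, 0)
  list(t = t, mean = m, se = se, df = N - 1, gap = !ok)
}

# Maximal suprathreshold runs of |t| and their strengths.
find_clusters <- function(tvec, thresh, grid) {
  hot <- abs(tvec) > thresh
  if (!any(hot)) {
    return(data.frame(start_ms = numeric(), end_ms = numeric(),
                      strength = numeric(), sign = numeric()))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  data.frame(
    start_ms = grid[starts[i]],
    end_ms = grid[ends[i]],
    strength = vapply(i, function(k) sum(abs(tvec[starts[k]:ends[k]])), 0),
    sign = vapply(i, function(k) sign(sum(tvec[starts[k]:ends[k]])), 0)
  )
}

# Permutation null of the maximum cluster strength under independent
# per-participant sign flips. Fully vectorized over permutations: with
# X = W*V, a sign row s gives weighted mean M = (s X) / colSums(W) and
#   sum_i w_i (s_i v_i - M)^2 = Q - 2 M (s X) + M^2 colSums(W),
# where Q = colSums(W V^2) is sign-invariant.
perm_null_max <- function(V, W, n_perm, thresh, seed = NULL) {
  N <- nrow(V); G <- ncol(V)
  cs <- colSums(W)
  ok <- cs > 0
  csx <- ifelse(ok, cs, 1)
  X <- W * V
  Q <- colSums(W * V^2)
  U <- sweep(W, 2, csx, "/")
  k2 <- colSums(U^2)
  denom <- pmax(1 - k2, .Machine$double.eps)
  with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * N, replace = TRUE), n_perm, N)
    A <- S %*% X
    M <- sweep(A, 2, csx, "/")
    SS <- matrix(Q, n_perm, G, byrow = TRUE) - 2 * M * A + sweep(M^2, 2, cs, "*")
    SS[SS < 0] <- 0          # numerical guard
    s2 <- sweep(sweep(SS, 2, csx, "/"), 2, denom, "/")
    Tm <- M / sqrt(sweep(s2, 2, k2, "*"))
    Tm[!is.finite(Tm)] <- 0
    Tm[, !ok] <- 0
    apply(Tm, 1, function(tv) {
      cl <- max_run_strength(tv, thresh)
      cl
    })
  })
}

# Max sum of |t| over contiguous runs with |t| > thresh (0 if none).
max_run_strength <- function(tvec, thresh) {
  hot <- abs(tvec) > thresh
  if (!any(hot)) return(0)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  max(vapply(i, function(k) sum(abs(tvec[starts[k]:ends[k]])), 0))
}

# Assemble the reported quadruple + per-cluster p-values into a result.
cluster_result <- function(obs, clusters, null_max, n_perm, grid, alpha, extra = list()) {
  t_crit <- as.numeric(stats::quantile(null_max, 0.95, names = FALSE))
  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$strength,
                         function(s) (1 + sum(null_max >= s)) / (n_perm + 1), 0)
    top <- which.max(clusters$strength)
    res <- list(p = clusters$p[top], t_obs = clusters$strength[top],
                t_crit = t_crit,
                window_ms = c(clusters$start_ms[top], clusters$end_ms[top]))
  } else {
    res <- list(p = 1, t_obs = 0, t_crit = t_crit, window_ms = c(NA_real_, NA_real_))
  }
  res$all_clusters <- clusters
  res$grid_ms <- grid
  res$t_series <- obs$t
  res$n_perm <- n_perm
  res$alpha <- alpha
  res <- c(res, extra)
  structure(res, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster-based permutation test\n")
  cat(sprintf("  grid: %g..%g ms, %d permutations, alpha = %g\n",
              min(x$grid_ms), max(x$grid_ms), x$n_perm, x$alpha))
  if (is.na(x$window_ms[1])) {
    cat(sprintf("  no suprathreshold cluster (t_crit = %.4g), p = 1\n", x$t_crit))
  } else {
    cat(sprintf("  p = %.4g, t = %.4g, t_crit = %.4g, window %g-%g ms\n",
                x$p, x$t_obs, x$t_crit, x$window_ms[1], x$window_ms[2]))
    if (nrow(x$all_clusters) > 1) {
      cat(sprintf("  (%d clusters in total)\n", nrow(x$all_clusters)))
    }
  }
  invisible(x)
}
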