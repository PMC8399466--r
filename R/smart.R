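#' Smooth one participant's endpoint-latency scatter onto a time grid
#'
#' Kernel-weighted moving average: at every grid time g the smoothed value
#' is the Gaussian-kernel weighted mean of the participant's endpoint values,
#' with weights K(g - t_i) for a Gaussian density of SD `kernel_sd_ms`
#' (truncated at 4 SD). The summed kernel mass at each grid point is kept
#' alongside the values: it quantifies how much data supports the estimate
#' there and later weights this participant's contribution to the group
#' series and to the pointwise test statistic.
#'
#' @param latency_ms saccade latencies (ms), one per trial.
#' @param value endpoint values (deg), same length.
#' @param kernel_sd_ms Gaussian kernel SD (ms); 16 for primary-saccade
#'   endpoint analyses, 32 for the more dispersed secondary saccades.
#' @param grid_ms evaluation grid (ms), typically 1-ms steps over the
#'   analysis window.
#' @param participant_id carried into the result.
#' @return object of class `smoothed_series`: list with `grid_ms`, `value`
#'   (NA where no kernel mass), `weight`, `participant_id`.
#' @export
smooth_individual <- function(latency_ms, value, kernel_sd_ms = 16,
                              grid_ms, participant_id = NA) {
  if (length(latency_ms) < 1) stop_named("empty_input", "no data points to smooth")
  stopifnot(length(latency_ms) == length(value), kernel_sd_ms > 0)
  d <- outer(grid_ms, latency_ms, "-")
  K <- stats::dnorm(d, sd = kernel_sd_ms)
  K[abs(d) > 4 * kernel_sd_ms] <- 0
  w <- rowSums(K)
  v <- as.numeric(K %*% value)
  v <- ifelse(w > 0, v / w, NA_real_)
  structure(list(grid_ms = grid_ms, value = v, weight = w,
                 participant_id = participant_id),
            class = "smoothed_series")
}

#' @export
print.smoothed_series <- function(x, ...) {
  cat(sprintf("Smoothed series (participant %s): %d grid points %g..%g ms, %.1f%% supported\n",
              as.character(x$participant_id), length(x$grid_ms),
              min(x$grid_ms), max(x$grid_ms), 100 * mean(x$weight > 0)))
  invisible(x)
}

#' Weighted group time series with pointwise confidence band
#'
#' At every grid point the group value is the kernel-mass weighted mean of
#' the participants' smoothed values, so participants with more trials near
#' that latency contribute more. The 95% band is the weighted mean plus or
#' minus t(0.975, N-1) times the weighted standard error (weighted variance
#' with effective-N correction).
#'
#' @param series list of `smoothed_series` on a common grid (N >= 2).
#' @param conf confidence level of the band.
#' @return list `grid_ms, value, ci_lower, ci_upper, weight` (`weight` is
#'   the summed kernel mass; grid points with zero total weight are NA in
#'   all three series and listed in attribute `gaps`).
#' @export
group_weighted_series <- function(series, conf = 0.95) {
  if (length(series) < 2) stop_named("too_few", "need >= 2 participants")
  sm <- series_matrix(series)
  st <- wt_stats(sm$V, sm$W)
  tq <- stats::qt(1 - (1 - conf) / 2, df = st$df)
  val <- ifelse(st$gap, NA_real_, st$mean)
  lo <- val - tq * st$se
  hi <- val + tq * st$se
  out <- list(grid_ms = sm$grid, value = val, ci_lower = lo, ci_upper = hi,
              weight = colSums(sm$W))
  attr(out, "gaps") <- sm$grid[st$gap]
  out
}

#' One-sample cluster-based permutation test on smoothed time courses
#'
#' Tests, at every grid point inside the analysis window, whether the
#' weighted group mean differs from `baseline`, using the weighted
#' one-sample t (df = N-1). Maximal runs where |t| exceeds the two-tailed
#' `alpha` quantile form clusters; cluster strength is the summed |t|. The
#' null distribution of the maximum cluster strength is built by randomly
#' sign-flipping each participant's deviation series `n_perm` times. Four
#' headline values are reported: the permutation p-value of the strongest
#' cluster (add-one convention, so never exactly zero), its strength
#' `t_obs`, the 95th percentile of the permutation distribution `t_crit`,
#' and the cluster's time window. All suprathreshold clusters are retained
#' in `all_clusters`.
#'
#' @param series list of `smoothed_series` (N >= 5 participants).
#' @param baseline null value tested against (deg).
#' @param window_ms analysis window (ms).
#' @param n_perm number of permutations (>= 100).
#' @param alpha cluster-forming alpha.
#' @param seed RNG seed for the permutation stream.
#' @return a `cluster_result`; also carries the group series with CI.
#' @export
cluster_test_onesample <- function(series, baseline = 0,
                                   window_ms = c(50, 300), n_perm = 10000,
                                   alpha = 0.05, seed = NULL) {
  if (length(series) < 5) stop_named("too_few", "need >= 5 participants")
  if (n_perm < 100) stop_named("bad_config", "n_perm must be >= 100")
  sm <- series_matrix(series, window_ms)
  V <- sm$V - baseline
  V[sm$W == 0] <- 0
  obs <- wt_stats(V, sm$W)
  thresh <- stats::qt(1 - alpha / 2, df = obs$df)
  clusters <- find_clusters(obs$t, thresh, sm$grid)
  null_max <- perm_null_max(V, sm$W, n_perm, thresh, seed = seed)
  grp <- group_weighted_series(series)
  keep <- grp$grid_ms >= window_ms[1] & grp$grid_ms <= window_ms[2]
  cluster_result(obs, clusters, null_max, n_perm, sm$grid, alpha,
                 extra = list(mean_series = grp$value[keep] ,
                              ci_lower = grp$ci_lower[keep],
                              ci_upper = grp$ci_upper[keep],
                              baseline = baseline))
}

#' Paired cluster-based permutation test on smoothed time courses
#'
#' Compares two conditions within participants by reducing each pair of
#' smoothed series to a difference series (A - B) whose weight at each grid
#' point is the smaller of the two condition weights (the difference is only
#' as well supported as its lesser condition), then runs the one-sample
#' machinery against 0. The permutation scheme - random condition-label
#' swaps per participant - is exactly a sign flip of the difference.
#'
#' @param seriesA,seriesB lists of `smoothed_series`, same participants in
#'   the same order, common grid.
#' @inheritParams cluster_test_onesample
#' @return a `cluster_result`.
#' @export
cluster_test_paired <- function(seriesA, seriesB, window_ms = c(50, 300),
                                n_perm = 10000, alpha = 0.05, seed = NULL) {
  if (length(seriesA) != length(seriesB)) {
    stop_named("bad_pairing", "condition series lists differ in length")
  }
  diff_series <- mapply(function(a, b) {
    if (!identical(a$grid_ms, b$grid_ms)) stop_named("grid_mismatch", "grids differ")
    w <- pmin(a$weight, b$weight)
    v <- a$value - b$value
    v[w == 0] <- NA_real_
    structure(list(grid_ms = a$grid_ms, value = v, weight = w,
                   participant_id = a$participant_id),
              class = "smoothed_series")
  }, seriesA, seriesB, SIMPLIFY = FALSE)
  cluster_test_onesample(diff_series, baseline = 0, window_ms = window_ms,
                         n_perm = n_perm, alpha = alpha, seed = seed)
}
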