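#' Distance-to-center time courses
#'
#' For every trial, the Euclidean distance between gaze and the image center
#' at each 1-ms grid point, averaged across trials within participant and
#' condition. Unlike the endpoint analyses this needs no smoothing: gaze is
#' sampled continuously, so there is data at every time point. Trials with
#' more than `max_missing` of their grid points missing are excluded and
#' reported; remaining gaps are averaged over.
#'
#' @param samples multi-trial sample table (`trial_id,t_ms,x_deg,y_deg`).
#' @param trials trial table with `trial_id`, `participant_id`, `condition`
#'   and image-center columns `center_x, center_y` (deg).
#' @param grid_ms evaluation grid, default 0..2000 ms.
#' @param max_missing maximum tolerated fraction of missing samples.
#' @return object of class `distance_timecourse`: list with `grid_ms`,
#'   `participants`, and `series` - a named list (one entry per condition)
#'   of participant x grid matrices - plus `excluded` (trial ids dropped for
#'   missingness).
#' @export
distance_timecourse <- function(samples, trials, grid_ms = 0:2000,
                                max_missing = 0.1) {
  need <- c("trial_id", "participant_id", "condition", "center_x", "center_y")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop_named("bad_trials", "trial table lacks: %s", paste(miss, collapse = ", "))
  by_trial <- split(samples, samples$trial_id)
  excluded <- character()
  dist_one <- function(tid) {
    s <- by_trial[[as.character(tid)]]
    tr <- trials[trials$trial_id == tid, ]
    out <- rep(NA_real_, length(grid_ms))
    if (!is.null(s)) {
      idx <- match(grid_ms, round(s$t_ms))
      hit <- !is.na(idx)
      out[hit] <- sqrt((s$x_deg[idx[hit]] - tr$center_x)^2 +
                       (s$y_deg[idx[hit]] - tr$center_y)^2)
    }
    if (mean(is.na(out)) > max_missing) {
      excluded <<- c(excluded, as.character(tid))
      return(NULL)
    }
    out
  }
  participants <- sort(unique(trials$participant_id))
  conditions <- sort(unique(trials$condition))
  series <- lapply(conditions, function(cond) {
    m <- t(vapply(participants, function(pid) {
      tids <- trials$trial_id[trials$participant_id == pid & trials$condition == cond]
      rows <- Filter(Negate(is.null), lapply(tids, dist_one))
      if (!length(rows)) return(rep(NA_real_, length(grid_ms)))
      colMeans(do.call(rbind, rows), na.rm = TRUE)
    }, numeric(length(grid_ms))))
    rownames(m) <- as.character(participants)
    m
  })
  names(series) <- conditions
  structure(list(grid_ms = grid_ms, participants = participants,
                 series = series, excluded = unique(excluded)),
            class = "distance_timecourse")
}

#' Dense paired cluster-based permutation test
#'
#' Compares two paired condition time courses sampled at every grid point
#' (e.g. distance-to-center series): pointwise paired t on the dense grid,
#' clusters of |t| above the two-tailed alpha quantile, summed-|t| cluster
#' strength, and a condition-label-swap permutation null - the same
#' conventions as the smoothed endpoint tests, but unweighted.
#'
#' @param tcA,tcB participant x grid matrices, same participants in the
#'   same row order.
#' @param grid_ms grid times (defaults to column index).
#' @param n_perm number of permutations.
#' @param alpha cluster-forming alpha.
#' @param seed RNG seed.
#' @return a `cluster_result`.
#' @export
dense_cluster_test <- function(tcA, tcB, grid_ms = NULL, n_perm = 10000,
                               alpha = 0.05, seed = NULL) {
  stopifnot(all(dim(tcA) == dim(tcB)))
  if (is.null(grid_ms)) grid_ms <- seq_len(ncol(tcA)) - 1
  D <- tcA - tcB
  W <- matrix(1, nrow(D), ncol(D))
  W[is.na(D)] <- 0
  D[is.na(D)] <- 0
  obs <- wt_stats(D, W)
  thresh <- stats::qt(1 - alpha / 2, df = obs$df)
  clusters <- find_clusters(obs$t, thresh, grid_ms)
  null_max <- perm_null_max(D, W, n_perm, thresh, seed = seed)
  cluster_result(obs, clusters, null_max, n_perm, grid_ms, alpha,
                 extra = list(mean_difference = obs$mean))
}

#' Saccade rate over the trial
#'
#' At every grid time, the fraction of trials in which gaze is inside a
#' saccade (between some event's onset and offset).
#'
#' @param events event table covering all trials.
#' @param trial_ids ids of all trials entering the denominator (trials
#'   without any event still count).
#' @param grid_ms evaluation grid (ms).
#' @return list `grid_ms, rate` with `rate` in [0, 1].
#' @export
saccade_rate <- function(events, trial_ids, grid_ms = 0:2000) {
  n_trials <- length(unique(trial_ids))
  counts <- numeric(length(grid_ms))
  g0 <- grid_ms[1]
  step <- if (length(grid_ms) > 1) grid_ms[2] - grid_ms[1] else 1
  for (i in seq_len(nrow(events))) {
    lo <- ceiling((events$onset_ms[i] - g0) / step) + 1
    hi <- floor((events$offset_ms[i] - g0) / step) + 1
    lo <- max(lo, 1); hi <- min(hi, length(grid_ms))
    if (lo <= hi) counts[lo:hi] <- counts[lo:hi] + 1
  }
  list(grid_ms = grid_ms, rate = counts / n_trials)
}

#' Spatial dwell-time heatmap
#'
#' Histogram of gaze samples over the image, in image-pixel coordinates
#' (origin top-left, x rightward, y downward), with square bins of
#' `bin_px` pixels; partial bins at the right/bottom edges are kept.
#' Counts are normalized to relative dwell probability (bins sum to 1 over
#' in-image samples); out-of-image samples are counted separately.
#'
#' @param x_px,y_px sample coordinates in image pixels.
#' @param image_px c(width, height) of the image in pixels.
#' @param bin_px bin size (default 40).
#' @return object of class `heatmap_grid`: list with `prob` (rows = y bins,
#'   cols = x bins), `bin_px`, `image_px`, `n_inside`, `n_outside`.
#' @export
spatial_heatmap <- function(x_px, y_px, image_px, bin_px = 40) {
  nx <- ceiling(image_px[1] / bin_px)
  ny <- ceiling(image_px[2] / bin_px)
  inside <- x_px >= 0 & x_px < image_px[1] & y_px >= 0 & y_px < image_px[2]
  ix <- pmin(floor(x_px[inside] / bin_px) + 1L, nx)
  iy <- pmin(floor(y_px[inside] / bin_px) + 1L, ny)
  counts <- matrix(0, ny, nx)
  tab <- table(factor(iy, levels = 1:ny), factor(ix, levels = 1:nx))
  counts[] <- as.numeric(tab)
  total <- sum(counts)
  structure(list(prob = if (total > 0) counts / total else counts,
                 bin_px = bin_px, image_px = image_px,
                 n_inside = sum(inside), n_outside = sum(!inside)),
            class = "heatmap_grid")
}

#' @rdname spatial_heatmap
#' @param a,b two `heatmap_grid` objects on the same grid.
#' @return signed difference matrix `a - b`.
#' @export
heatmap_difference <- function(a, b) {
  stopifnot(all(dim(a$prob) == dim(b$prob)))
  a$prob - b$prob
}

#' Exploration quality over the course of the experiment
#'
#' Per sequential bin of trials (16 bins of 32 trials for the full design):
#' mean saccadic amplitude and mean number of saccades per trial, counting
#' only saccades with amplitude of at least `min_amp_deg` (1 deg by
#' default, excluding microsaccades).
#'
#' @param events event table.
#' @param trial_order trial ids in presentation order.
#' @param min_amp_deg amplitude floor (deg).
#' @param n_bins number of sequential bins.
#' @return data.frame `bin, n_trials, mean_amplitude_deg,
#'   mean_saccades_per_trial` (amplitude is NA for bins without qualifying
#'   saccades).
#' @export
exploration_metrics <- function(events, trial_order, min_amp_deg = 1, n_bins = 16) {
  ev <- events[events$amplitude_deg >= min_amp_deg, , drop = FALSE]
  n <- length(trial_order)
  bin_of <- ceiling(seq_len(n) / (n / n_bins))
  per_trial_count <- vapply(trial_order, function(tid) sum(ev$trial_id == tid), 0)
  rows <- lapply(seq_len(n_bins), function(b) {
    tids <- trial_order[bin_of == b]
    amps <- ev$amplitude_deg[ev$trial_id %in% tids]
    data.frame(bin = b, n_trials = length(tids),
               mean_amplitude_deg = if (length(amps)) mean(amps) else NA_real_,
               mean_saccades_per_trial = mean(per_trial_count[bin_of == b]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
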