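make_dist_fixture <- function(pos, center = c(0, 0), n_ms = 200) {
  samples <- data.frame(trial_id = "t1", t_ms = 0:(n_ms - 1),
                        x_deg = pos[1], y_deg = pos[2])
  trials <- data.frame(trial_id = "t1", participant_id = "p1",
                       condition = "explore", center_x = center[1],
                       center_y = center[2], stringsAsFactors = FALSE)
  list(samples = samples, trials = trials)
}

test_that("distance to center is exact for fixed gaze", {
  f0 <- make_dist_fixture(c(0, 0))
  d0 <- distance_timecourse(f0$samples, f0$trials, grid_ms = 0:199)
  expect_true(all(d0$series$explore == 0))
  f1 <- make_dist_fixture(c(3, 4))
  d1 <- distance_timecourse(f1$samples, f1$trials, grid_ms = 0:199)
  expect_true(all(abs(d1$series$explore - 5) < 1e-12))
})

test_that("distance series matches a sample-wise hand computation and is
           translation-equivariant", {
  fx <- data.frame(x_deg = c(0, 4, -2), y_deg = c(0, 1, 2),
                   duration_ms = c(300, 400, 500))
  tr <- generate_gaze_trace(fx, sample_noise_sd = 0, seed = 1, trial_id = "t1")
  trials <- data.frame(trial_id = "t1", participant_id = "p1",
                       condition = "explore", center_x = 1, center_y = -1,
                       stringsAsFactors = FALSE)
  g <- 0:1000
  dt <- distance_timecourse(tr$samples, trials, grid_ms = g)
  hand <- sqrt((tr$samples$x_deg[g + 1] - 1)^2 + (tr$samples$y_deg[g + 1] + 1)^2)
  expect_equal(as.numeric(dt$series$explore), hand, tolerance = 1e-12)
  # rigid translation of scanpath and center leaves distances unchanged
  s2 <- tr$samples; s2$x_deg <- s2$x_deg + 5; s2$y_deg <- s2$y_deg - 3
  t2 <- trials; t2$center_x <- t2$center_x + 5; t2$center_y <- t2$center_y - 3
  dt2 <- distance_timecourse(s2, t2, grid_ms = g)
  expect_equal(dt2$series$explore, dt$series$explore, tolerance = 1e-12)
})

test_that("trials with too many missing samples are excluded and reported", {
  f <- make_dist_fixture(c(1, 1), n_ms = 200)
  f$samples <- f$samples[f$samples$t_ms < 100, ]   # 50% missing
  d <- distance_timecourse(f$samples, f$trials, grid_ms = 0:199)
  expect_equal(d$excluded, "t1")
})

test_that("dense cluster test is null for identical inputs and finds offsets", {
  set.seed(61)
  A <- matrix(rnorm(10 * 500, 5, 1), 10, 500)
  ct0 <- dense_cluster_test(A, A, n_perm = 200, seed = 2)
  expect_equal(ct0$p, 1)
  B <- A + rnorm(5000, 0, 1)
  B[, 300:500] <- B[, 300:500] - 0.8
  ct1 <- dense_cluster_test(A, B, grid_ms = 0:499, n_perm = 200, seed = 2)
  expect_lt(ct1$p, 0.05)
  expect_lt(ct1$window_ms[1], 450)
  expect_gt(ct1$window_ms[2], 320)
})

test_that("dense test reduces to the smoothed paired test under uniform weights", {
  set.seed(71)
  g <- 0:99
  A <- matrix(rnorm(8 * 100), 8, 100)
  B <- matrix(rnorm(8 * 100, 0.3), 8, 100)
  mk <- function(m, p) structure(list(grid_ms = g, value = m[p, ],
                                      weight = rep(1, 100), participant_id = p),
                                 class = "smoothed_series")
  ctd <- dense_cluster_test(A, B, grid_ms = g, n_perm = 300, seed = 9)
  cts <- cluster_test_paired(lapply(1:8, mk, m = A), lapply(1:8, mk, m = B),
                             window_ms = c(0, 99), n_perm = 300, seed = 9)
  expect_equal(ctd$t_series, cts$t_series, tolerance = 1e-10)
  expect_equal(ctd$p, cts$p)
  expect_equal(ctd$window_ms, cts$window_ms)
})

test_that("saccade rate counts trials inside saccades", {
  ids <- c("a", "b", "c")
  expect_true(all(saccade_rate(data.frame(trial_id = character(),
                                          onset_ms = numeric(), offset_ms = numeric(),
                                          amplitude_deg = numeric()),
                               ids, 0:100)$rate == 0))
  ev <- data.frame(trial_id = ids, onset_ms = 100, offset_ms = 150)
  r <- saccade_rate(ev, ids, 0:300)
  expect_true(all(r$rate[101:151] == 1))
  expect_true(all(r$rate[c(1:100, 152:301)] == 0))
})

test_that("saccade rate asymptote matches the analytic schedule expectation", {
  # 3 saccades/s of ~33 ms each -> asymptotic rate about 0.1
  set.seed(5)
  evs <- lapply(1:200, function(i) {
    onsets <- seq(100, 1900, by = 333) + runif(6, 0, 80)
    data.frame(trial_id = sprintf("t%03d", i), onset_ms = onsets,
               offset_ms = onsets + 33)
  })
  r <- saccade_rate(do.call(rbind, evs), sprintf("t%03d", 1:200), 0:2000)
  expect_equal(mean(r$rate[500:1500]), 0.1, tolerance = 0.02)
})

test_that("heatmaps are normalized dwell histograms", {
  h1 <- spatial_heatmap(rep(10, 50), rep(10, 50), image_px = c(800, 720))
  expect_equal(h1$prob[1, 1], 1)
  expect_equal(sum(h1$prob), 1)
  expect_equal(dim(h1$prob), c(18, 20))
  set.seed(3)
  x <- runif(20000, 0, 800); y <- runif(20000, 0, 720)
  hu <- spatial_heatmap(x, y, c(800, 720))
  expect_equal(sum(hu$prob), 1)
  # approximately flat: chi-square sanity bound on uniform dwell
  exp_p <- 1 / (18 * 20)
  chi <- sum((hu$prob - exp_p)^2 / exp_p) * 20000
  expect_lt(chi, qchisq(0.999, 18 * 20 - 1))
  expect_true(all(heatmap_difference(hu, hu) == 0))
  # out-of-image samples are excluded but counted
  ho <- spatial_heatmap(c(10, -5, 900), c(10, 10, 10), c(800, 720))
  expect_equal(ho$n_inside, 1)
  expect_equal(ho$n_outside, 2)
})

test_that("exploration metrics bin trials sequentially and filter microsaccades", {
  ids <- sprintf("t%03d", 1:512)
  # all amplitudes below 1 degree -> everything filtered out
  ev_small <- data.frame(trial_id = ids, onset_ms = 100, offset_ms = 130,
                         amplitude_deg = 0.5)
  m0 <- exploration_metrics(ev_small, ids)
  expect_true(all(m0$mean_saccades_per_trial == 0))
  expect_equal(nrow(m0), 16)
  expect_true(all(m0$n_trials == 32))
  # constructed amplitudes: trial i has one saccade of i/100 deg
  ev <- data.frame(trial_id = ids, onset_ms = 100, offset_ms = 130,
                   amplitude_deg = (1:512) / 100)
  m <- exploration_metrics(ev, ids)
  # first bin: trials 1..32, amplitudes .01...32 all < 1 -> zero saccades
  expect_equal(m$mean_saccades_per_trial[1], 0)
  # last bin: trials 481..512 -> amplitudes 4.81..5.12, mean 4.965
  expect_equal(m$mean_amplitude_deg[16], mean((481:512) / 100))
  expect_equal(m$mean_saccades_per_trial[16], 1)
})
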