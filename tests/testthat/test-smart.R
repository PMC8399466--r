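test_that("kernel smoothing reduces to the point values in trivial cases", {
  g <- 0:400
  s1 <- make_series(150, 1.0, grid = g)
  expect_true(all(abs(s1$value[s1$weight > 0] - 1) < 1e-12))
  expect_true(all(is.na(s1$value[s1$weight == 0])))
  # two symmetric points: midpoint value is their average
  s2 <- make_series(c(100, 300), c(0, 2), grid = g, sd = 60)
  expect_equal(s2$value[g == 200], 1.0)
  expect_error(smooth_individual(numeric(0), numeric(0), 16, g), class = "empty_input")
})

test_that("kernel smoothing matches a brute-force double loop", {
  set.seed(5)
  lat <- runif(50, 60, 290); val <- rnorm(50)
  g <- 50:300
  s <- make_series(lat, val, grid = g)
  brute_v <- brute_w <- numeric(length(g))
  for (i in seq_along(g)) {
    num <- den <- 0
    for (j in seq_along(lat)) {
      d <- g[i] - lat[j]
      k <- if (abs(d) > 64) 0 else dnorm(d, sd = 16)
      num <- num + k * val[j]; den <- den + k
    }
    brute_v[i] <- if (den > 0) num / den else NA
    brute_w[i] <- den
  }
  expect_equal(s$value, brute_v, tolerance = 1e-10)
  expect_equal(s$weight, brute_w, tolerance = 1e-10)
})

test_that("smoothing is order-invariant and affine-equivariant", {
  set.seed(8)
  lat <- runif(30, 60, 290); val <- rnorm(30); g <- 50:300
  perm <- sample(30)
  expect_equal(make_series(lat, val, g)$value,
               make_series(lat[perm], val[perm], g)$value)
  a <- 2.5; b <- -1
  expect_equal(make_series(lat, a * val + b, g)$value,
               a * make_series(lat, val, g)$value + b)
})

test_that("group series is the weighted mean with a degenerate CI when identical", {
  g <- 50:300
  set.seed(2)
  lat <- runif(40, 60, 290); val <- rnorm(40)
  same <- lapply(1:4, function(p) make_series(lat, val, g, pid = p))
  grp <- group_weighted_series(same)
  base <- same[[1]]$value
  expect_equal(grp$value, base)
  hw <- grp$ci_upper - grp$ci_lower
  expect_true(all(hw[!is.na(hw)] < 1e-8))
  # two participants, weights 3 and 1, values 0 and 4 -> mean 1
  mk <- function(w, v, pid) structure(list(grid_ms = 0, value = v, weight = w,
                                           participant_id = pid), class = "smoothed_series")
  grp2 <- group_weighted_series(list(mk(3, 0, 1), mk(1, 4, 2)))
  expect_equal(grp2$value, 1.0)
})

test_that("group weighted mean matches a brute-force average on random data", {
  g <- 50:150
  set.seed(13)
  series <- lapply(1:6, function(p)
    make_series(runif(30, 40, 200), rnorm(30), g, pid = p))
  grp <- group_weighted_series(series)
  for (i in c(1, 37, 101)) {
    num <- sum(vapply(series, function(s) s$weight[i] * ifelse(is.na(s$value[i]), 0, s$value[i]), 0))
    den <- sum(vapply(series, function(s) s$weight[i], 0))
    expect_equal(grp$value[i], num / den, tolerance = 1e-10)
  }
})

test_that("zero-variance data at baseline produce no cluster", {
  g <- 50:300
  series <- lapply(1:6, function(p) make_series(runif(50, 60, 290), rep(0, 50), g, pid = p))
  ct <- cluster_test_onesample(series, baseline = 0, window_ms = c(50, 300),
                               n_perm = 200, seed = 1)
  expect_equal(ct$p, 1)
  expect_equal(ct$t_obs, 0)
  expect_true(all(is.na(ct$window_ms)))
})

test_that("an injected bias window is found where it was injected", {
  g <- 50:300
  set.seed(21)
  series <- lapply(1:18, function(p) {
    lat <- rnorm(200, 160, 50)
    bias <- ifelse(lat >= 100 & lat <= 200, 1.5, 0)
    make_series(lat, bias + rnorm(200, 0, 0.7), g, pid = p)
  })
  ct <- cluster_test_onesample(series, 0, c(50, 300), n_perm = 300, seed = 5)
  expect_lt(ct$p, 0.05)
  expect_lt(ct$window_ms[1], 200)
  expect_gt(ct$window_ms[2], 100)
  # window always inside the analysis window
  expect_gte(ct$window_ms[1], 50)
  expect_lte(ct$window_ms[2], 300)
  # reproducible bit-exactly under the same seed
  ct2 <- cluster_test_onesample(series, 0, c(50, 300), n_perm = 300, seed = 5)
  expect_identical(ct[c("p", "t_obs", "t_crit", "window_ms")],
                   ct2[c("p", "t_obs", "t_crit", "window_ms")])
})

test_that("paired test is null for identical conditions and detects an offset", {
  g <- 50:300
  set.seed(31)
  A <- lapply(1:8, function(p) make_series(runif(100, 60, 290), rnorm(100, 0, 0.5), g, pid = p))
  ct0 <- cluster_test_paired(A, A, c(50, 300), n_perm = 200, seed = 3)
  expect_equal(ct0$p, 1)
  B <- lapply(1:8, function(p) {
    # constant 1 deg offset plus a little independent participant noise
    # (a perfectly constant difference has zero between-participant
    # variance, where the t statistic is undefined)
    s <- A[[p]]; s$value <- s$value + 1 + rnorm(length(s$value), 0, 0.02); s
  })
  ct1 <- cluster_test_paired(A, B, c(50, 300), n_perm = 200, seed = 3)
  expect_lt(ct1$p, 0.05)
  # offset spans the full window -> cluster covers (nearly) all of it
  expect_lte(ct1$window_ms[1], 60)
  expect_gte(ct1$window_ms[2], 290)
  # label-swap symmetry: swapping conditions preserves p and the window
  ct2 <- cluster_test_paired(B, A, c(50, 300), n_perm = 200, seed = 3)
  expect_equal(ct1$p, ct2$p)
  expect_equal(ct1$window_ms, ct2$window_ms)
  expect_equal(ct1$t_series, -ct2$t_series)
})

test_that("t_crit stabilizes as the permutation count grows", {
  g <- 50:300
  series <- null_series(10, 100, grid = g, seed = 44)
  crits <- vapply(1:16, function(i)
    cluster_test_onesample(series, 0, c(50, 300), n_perm = 300, seed = i)$t_crit, 0)
  crits2 <- vapply(1:16, function(i)
    cluster_test_onesample(series, 0, c(50, 300), n_perm = 3000, seed = i)$t_crit, 0)
  expect_lt(sd(crits2), sd(crits))
})
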