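test_that("binning follows the half-open convention with closed last bin", {
  b <- bin_endpoints(c(-2.5, 2.5))
  expect_equal(b$counts[1], 1)
  expect_equal(b$counts[20], 1)
  expect_equal(b$n_total, 2)
  b2 <- bin_endpoints(c(rep(0.1, 38), 3, 3.2))
  expect_equal(b2$n_total, 38)
  expect_equal(b2$n_outside, 2)
  expect_error(bin_endpoints(1, edges = c(0, 0, 1)), class = "bad_edges")
})

test_that("binning matches a brute-force histogram on random data", {
  set.seed(17)
  x <- runif(500, -2.5, 2.5)
  edges <- seq(-2.5, 2.5, length.out = 21)
  b <- bin_endpoints(x, edges)
  brute <- vapply(1:20, function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    if (i < 20) sum(x >= lo & x < hi) else sum(x >= lo & x <= hi)
  }, 0)
  expect_equal(b$counts, brute)
  expect_equal(sum(b$counts), b$n_total)
})

test_that("a noiseless single Gaussian is recovered to high precision", {
  edges <- seq(-2.5, 2.5, length.out = 21)
  ctr <- (edges[-1] + edges[-21]) / 2
  truth <- list(mu = 0.5, sigma = 0.6, a = 30)
  b <- structure(list(edges = edges, centers = ctr,
                      counts = truth$a * dnorm((ctr - truth$mu) / truth$sigma),
                      n_total = 100, n_outside = 0), class = "binned_endpoints")
  f <- fit_scaled_gaussians(b)
  expect_lt(abs(f$single$params[["mu"]] - 0.5), 1e-3)
  expect_lt(abs(f$single$params[["sigma"]] - 0.6), 1e-3)
  expect_lt(abs(f$single$params[["a"]] - 30), 1e-2)
  expect_lt(f$single$rss, 1e-6)
})

test_that("well-separated bimodal counts favor the dual model", {
  edges <- seq(-2.5, 2.5, length.out = 21)
  ctr <- (edges[-1] + edges[-21]) / 2
  counts <- 25 * dnorm(ctr / 0.4) + 20 * dnorm((ctr - 2) / 0.4)
  b <- structure(list(edges = edges, centers = ctr, counts = counts,
                      n_total = 120, n_outside = 0), class = "binned_endpoints")
  f <- fit_scaled_gaussians(b)
  expect_lt(f$dual$bic, f$single$bic)
  # canonical order mu1 <= mu2
  expect_lte(f$dual$params[["mu1"]], f$dual$params[["mu2"]])
  # dual model nests the single model: two components with equal means and
  # split scales predict the same curve, hence the same RSS
  mu <- f$single$params[["mu"]]; s <- f$single$params[["sigma"]]
  a <- f$single$params[["a"]]
  pred_dual <- gazebias:::scaled_gaussian(ctr, mu, s, 0.3 * a) +
    gazebias:::scaled_gaussian(ctr, mu, s, 0.7 * a)
  pred_single <- gazebias:::scaled_gaussian(ctr, mu, s, a)
  expect_equal(pred_dual, pred_single, tolerance = 1e-12)
  expect_lte(f$dual$rss, f$single$rss + 1e-8)
})

test_that("a one-bin spike drives sigma to its bound and is flagged", {
  edges <- seq(-2.5, 2.5, length.out = 21)
  counts <- rep(0, 20); counts[10] <- 50
  b <- structure(list(edges = edges, centers = (edges[-1] + edges[-21]) / 2,
                      counts = counts, n_total = 50, n_outside = 0),
                 class = "binned_endpoints")
  f <- fit_scaled_gaussians(b)
  expect_true(f$single$degenerate)
})

test_that("information weights follow the BIC formula", {
  w <- information_weights(100, 100)
  expect_equal(c(w$w_single, w$w_dual), c(0.5, 0.5))
  # Delta BIC = 2 in favor of single: w_single = 1 / (1 + exp(-1)) = 0.731
  w2 <- information_weights(100, 102)
  expect_equal(w2$w_single, 1 / (1 + exp(-1)), tolerance = 1e-6)
  expect_equal(round(w2$w_single, 3), 0.731)
  w3 <- information_weights(0, 1e6)
  expect_equal(w3$w_single, 1)
  expect_equal(w3$w_single + w3$w_dual, 1)
})

test_that("signed-rank comparison handles the exact small-sample cases", {
  # 3 pairs all favoring single: only 1 of 8 sign patterns is as extreme in
  # either direction -> two-sided exact p = 2/8
  r <- group_comparison(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(r$p, 0.25)
  expect_equal(r$n_favoring_single, 3)
  # antisymmetric pairs -> Z = 0
  r2 <- group_comparison(c(0.6, 0.6, 0.4, 0.4), c(0.4, 0.4, 0.6, 0.6))
  expect_equal(r2$Z, 0)
  # all-equal pairs -> degenerate p = 1
  r3 <- group_comparison(rep(0.5, 6), rep(0.5, 6))
  expect_equal(r3$p, 1)
})

test_that("signed-rank statistic and p agree with the reference implementation", {
  set.seed(23)
  for (n in c(8, 18)) {
    a <- runif(n); b <- runif(n)
    ours <- group_comparison(a, b)
    # V statistic must match exactly
    ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    expect_equal(ours$V, unname(ref$statistic))
    refp <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                         exact = n < 10, correct = TRUE))
    expect_equal(ours$p, refp$p.value, tolerance = 1e-6)
  }
})

test_that("generated bias and capture data are attributed to the right model", {
  # one participant per mode at realistic in-cluster trial counts
  base <- bias_profile(amplitude = 0.5, t_peak_ms = 150, width_ms = 1e6)
  for (mode in c("bias", "capture")) {
    p <- generator_params(mode = mode, n_trials = 150, separation_deg = 2,
                          profile = base)
    g <- generate_endpoint_trials(p, seed = 77)
    rec <- recode_endpoints(g$events, g$trials)
    f <- fit_scaled_gaussians(bin_endpoints(rec$endpoint_rel_deg))
    w <- information_weights(f$single$bic, f$dual$bic)
    expect_equal(w$winner, if (mode == "bias") "single" else "dual")
  }
})
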