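#' Bin recoded endpoints into the standard histogram
#'
#' 20 equally sized bins between -2.5 and +2.5 deg by default. Bins are
#' half-open [lo, hi) with the last bin closed, so -2.5 lands in the first
#' bin and +2.5 in the last. Values outside the range are excluded and
#' counted.
#'
#' @param values recoded endpoint values (deg).
#' @param edges strictly increasing bin edges (21 values for the default).
#' @return object of class `binned_endpoints`: list with `edges`, `centers`,
#'   `counts`, `n_total` (in-range count) and `n_outside`.
#' @export
bin_endpoints <- function(values, edges = seq(-2.5, 2.5, length.out = 21)) {
  if (any(diff(edges) <= 0)) stop_named("bad_edges", "edges must be strictly increasing")
  inside <- values >= edges[1] & values <= edges[length(edges)]
  x <- values[inside]
  idx <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 n_total = sum(counts),
                 n_outside = sum(!inside)),
            class = "binned_endpoints")
}

# Scaled Gaussian profile evaluated at bin centers: a * phi((c - mu) / sigma)
# with phi the standard normal density; the scale parameter absorbs the
# normalization, so `a` is in count units.
scaled_gaussian <- function(centers, mu, sigma, a) a * stats::dnorm((centers - mu) / sigma)

#' Fit single- and dual-Gaussian models to an endpoint histogram
#'
#' Fits scaled Gaussians to the binned counts. The single-Gaussian ("bias")
#' model has three free parameters (mean, SD, scale); the dual-Gaussian
#' ("capture") model has five (two means, two scales, one shared SD -
#' oculomotor variability is assumed identical whichever target is
#' selected; a free-SD variant is available via `shared_sigma = FALSE`).
#'
#' The default loss is the Poisson deviance of the bin counts, which
#' matches their sampling noise (count variance scales with the expected
#' count); ordinary least squares on the counts is available via
#' `loss = "least_squares"`. With least squares the count noise is
#' heteroscedastic relative to the loss, which lets the flexible dual model
#' absorb noise in the well-filled central bins and noticeably weakens the
#' unimodal/bimodal discrimination - hence the likelihood default.
#'
#' Optimization is L-BFGS-B from multiple starts: the single model from the
#' histogram's moment estimates, the dual model from mean pairs (0, d) and
#' (-d/2, d/2) with `d` the nominal goal-to-attractor separation, each plus
#' jittered restarts. Model quality is summarized per loss as
#' BIC = deviance + k log(n) (Poisson) or BIC = n log(RSS/n) + k log(n)
#' (least squares), over the n = 20 bins.
#'
#' @param binned a [bin_endpoints()] result (n_total >= 20 recommended).
#' @param separation_deg nominal separation d used to seed the dual means.
#' @param n_restarts jittered restarts per start point.
#' @param shared_sigma if FALSE the dual model gets a sixth parameter.
#' @param loss `"poisson"` (default) or `"least_squares"`.
#' @param seed RNG seed for the jitter.
#' @return list with elements `single` and `dual`, each a `mixture_fit`:
#'   `model`, `params`, `rss`, `bic`, `n_free`, `degenerate` (sigma at its
#'   lower bound).
#' @export
fit_scaled_gaussians <- function(binned, separation_deg = 2, n_restarts = 8,
                                 shared_sigma = TRUE,
                                 loss = c("poisson", "least_squares"),
                                 seed = 1L) {
  loss <- match.arg(loss)
  ctr <- binned$centers
  y <- binned$counts
  n <- length(y)
  if (binned$n_total < 1) stop_named("empty_input", "no counts to fit")
  lo_mu <- min(binned$edges); hi_mu <- max(binned$edges)
  lo_sig <- 0.05; hi_sig <- 3
  hi_a <- 10 * max(y, 1)

  objective <- function(pred) {
    if (loss == "poisson") {
      lam <- pmax(pred, 1e-9)
      sum(lam - y * log(lam))
    } else {
      sum((y - pred)^2)
    }
  }
  rss_single <- function(p) objective(scaled_gaussian(ctr, p[1], p[2], p[3]))
  rss_dual <- function(p) {
    sig1 <- p[5]; sig2 <- if (shared_sigma) p[5] else p[6]
    objective(scaled_gaussian(ctr, p[1], sig1, p[3]) +
              scaled_gaussian(ctr, p[2], sig2, p[4]))
  }

  run_optim <- function(fn, start, lower, upper) {
    fit <- try(stats::optim(pmin(pmax(start, lower), upper), fn, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) NULL else fit
  }

  # moment start for the single model
  w <- y / max(sum(y), 1)
  mu0 <- sum(w * ctr)
  sd0 <- sqrt(max(sum(w * (ctr - mu0)^2), lo_sig^2))
  best <- function(fn, starts, lower, upper) {
    fits <- Filter(Negate(is.null), lapply(starts, run_optim, fn = fn,
                                           lower = lower, upper = upper))
    if (!length(fits)) stop_named("no_convergence", "all optimizer starts failed")
    fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  }

  with_seed(seed, {
    jitter_starts <- function(base, scale) {
      c(list(base),
        lapply(seq_len(n_restarts), function(i) base + stats::rnorm(length(base), 0, scale)))
    }
    s_lower <- c(lo_mu, lo_sig, 0); s_upper <- c(hi_mu, hi_sig, hi_a)
    s_fit <- best(rss_single, jitter_starts(c(mu0, sd0, max(y)), c(0.3, 0.2, max(y) / 5)),
                  s_lower, s_upper)

    d <- separation_deg
    d_base <- list(c(0, d, max(y), max(y) / 2, sd0),
                   c(-d / 2, d / 2, max(y), max(y), sd0))
    if (!shared_sigma) d_base <- lapply(d_base, function(b) c(b, sd0))
    d_lower <- c(lo_mu, lo_mu, 0, 0, lo_sig); d_upper <- c(hi_mu, hi_mu, hi_a, hi_a, hi_sig)
    if (!shared_sigma) { d_lower <- c(d_lower, lo_sig); d_upper <- c(d_upper, hi_sig) }
    d_starts <- unlist(lapply(d_base, jitter_starts,
                              scale = c(0.3, 0.3, max(y) / 5, max(y) / 5, 0.2,
                                        if (!shared_sigma) 0.2)), recursive = FALSE)
    d_fit <- best(rss_dual, d_starts, d_lower, d_upper)

    mk <- function(model, par, obj, k, pred) {
      rss <- sum((y - pred)^2)
      bic <- if (loss == "poisson") 2 * obj + k * log(n) else
        n * log(max(rss, 1e-12) / n) + k * log(n)
      structure(list(model = model, params = par, rss = rss, bic = bic,
                     n_free = k,
                     degenerate = any(abs(par[grep("sigma", names(par))] - lo_sig) < 1e-8)),
                class = "mixture_fit")
    }
    sp <- s_fit$par; names(sp) <- c("mu", "sigma", "a")
    single <- mk("single", sp, s_fit$value, 3L,
                 scaled_gaussian(ctr, sp[["mu"]], sp[["sigma"]], sp[["a"]]))

    dp <- d_fit$par
    names(dp) <- if (shared_sigma) c("mu1", "mu2", "a1", "a2", "sigma") else
      c("mu1", "mu2", "a1", "a2", "sigma1", "sigma2")
    if (dp[["mu1"]] > dp[["mu2"]]) {   # canonical order mu1 <= mu2
      dp[c("mu1", "mu2")] <- dp[c("mu2", "mu1")]
      dp[c("a1", "a2")] <- dp[c("a2", "a1")]
      if (!shared_sigma) dp[c("sigma1", "sigma2")] <- dp[c("sigma2", "sigma1")]
    }
    sig1 <- dp[[if (shared_sigma) "sigma" else "sigma1"]]
    sig2 <- dp[[if (shared_sigma) "sigma" else "sigma2"]]
    dual <- mk("dual", dp, d_fit$value, if (shared_sigma) 5L else 6L,
               scaled_gaussian(ctr, dp[["mu1"]], sig1, dp[["a1"]]) +
                 scaled_gaussian(ctr, dp[["mu2"]], sig2, dp[["a2"]]))
    list(single = single, dual = dual)
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%s-Gaussian fit: RSS = %.4g, BIC = %.4g (%d free)%s\n",
              x$model, x$rss, x$bic, x$n_free,
              if (x$degenerate) " [degenerate sigma]" else ""))
  print(round(x$params, 4))
  invisible(x)
}

#' BIC information weights for the single/dual model pair
#'
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2) with
#' Delta_i = BIC_i - min(BIC). Weights sum to 1; higher is more evidence.
#'
#' @param bic_single,bic_dual finite BIC values.
#' @return list `w_single, w_dual, winner`.
#' @export
information_weights <- function(bic_single, bic_dual) {
  stopifnot(is.finite(bic_single), is.finite(bic_dual))
  d <- c(bic_single, bic_dual) - min(bic_single, bic_dual)
  e <- exp(-d / 2)
  w <- e / sum(e)
  list(w_single = w[1], w_dual = w[2],
       winner = if (w[1] >= w[2]) "single" else "dual")
}

#' Wilcoxon signed-rank comparison of paired information weights
#'
#' Group-level test of whether one model systematically wins: two-sided
#' signed-rank test on the per-participant differences w_single - w_dual.
#' Zero differences are dropped, ties get average ranks; for N >= 10 the
#' continuity-corrected normal approximation is used (with tie correction),
#' below that the exact null distribution is enumerated over all sign
#' patterns. Also reports how many participants favor each model.
#'
#' @param w_single,w_dual paired weight vectors (N >= 3 pairs).
#' @return list `n_favoring_single, n_favoring_dual, V, Z, p, method`.
#' @export
group_comparison <- function(w_single, w_dual) {
  stopifnot(length(w_single) == length(w_dual))
  if (length(w_single) < 3) stop_named("too_few", "need >= 3 pairs")
  d <- w_single - w_dual
  n_fav_s <- sum(d > 0); n_fav_d <- sum(d < 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(n_favoring_single = n_fav_s, n_favoring_dual = n_fav_d,
                V = NA_real_, Z = 0, p = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n < 10) {
    # exact: enumerate all 2^n sign assignments of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    null_V <- as.numeric(signs %*% r)
    mu <- n * (n + 1) / 4
    p <- mean(abs(null_V - mu) >= abs(V - mu) - 1e-12)
    z <- (V - mu) / stats::sd(null_V)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(n_favoring_single = n_fav_s, n_favoring_dual = n_fav_d,
       V = V, Z = z, p = min(p, 1), method = method)
}

#' Per-participant endpoint model comparison
#'
#' Convenience wrapper: bins each participant's in-window recoded endpoints,
#' fits both models and computes information weights.
#'
#' @param endpoints recoded endpoint table with `participant_id`,
#'   `endpoint_rel_deg` and `latency_ms`.
#' @param window_ms latency window (typically the significant cluster from
#'   the time-course test); NULL keeps all trials.
#' @param edges histogram edges.
#' @param separation_deg dual-model seeding separation.
#' @param seed RNG seed for optimizer jitter.
#' @return data.frame per participant: `participant_id, w_single, w_dual,
#'   winner, bic_single, bic_dual, n_trials`.
#' @export
compare_endpoint_models <- function(endpoints, window_ms = NULL,
                                    edges = seq(-2.5, 2.5, length.out = 21),
                                    separation_deg = 2, seed = 1L) {
  if (!is.null(window_ms)) {
    endpoints <- endpoints[endpoints$latency_ms >= window_ms[1] &
                           endpoints$latency_ms <= window_ms[2], , drop = FALSE]
  }
  parts <- split(endpoints, endpoints$participant_id)
  rows <- lapply(names(parts), function(pid) {
    b <- bin_endpoints(parts[[pid]]$endpoint_rel_deg, edges)
    f <- fit_scaled_gaussians(b, separation_deg = separation_deg,
                              seed = derive_seed(seed, pid))
    w <- information_weights(f$single$bic, f$dual$bic)
    data.frame(participant_id = pid, w_single = w$w_single, w_dual = w$w_dual,
               winner = w$winner, bic_single = f$single$bic,
               bic_dual = f$dual$bic, n_trials = b$n_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
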