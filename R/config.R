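#' Analysis configuration
#'
#' Bundles the tunable parameters of the whole pipeline: the Gaussian kernel
#' SD used to smooth endpoint time courses (16 ms for primary saccades, 32 ms
#' for the more widely distributed secondary saccades), the 1-ms analysis
#' grid, the number of permutations (10,000 by default), the cluster-forming
#' alpha, the latency analysis window, the endpoint histogram bin edges
#' (20 equal bins between -2.5 and +2.5 deg), trial-filter thresholds
#' (minimum horizontal amplitude 6 deg; maximum deviation from the midline on
#' the analysis axis 4 deg), and the master RNG seed.
#'
#' @param kernel_sd_ms Gaussian kernel SD in ms.
#' @param grid_step_ms grid resolution in ms.
#' @param n_permutations permutations per cluster test.
#' @param alpha cluster-forming (and reporting) alpha level.
#' @param analysis_window_ms length-2 numeric, latency window (ms).
#' @param bin_edges endpoint histogram bin edges (deg).
#' @param min_horiz_amp_deg trial filter: minimum horizontal amplitude (deg).
#' @param max_axis_dev_deg trial filter: maximum endpoint deviation from the
#'   midline on the analysis axis (deg).
#' @param anticipatory_cut_ms latencies strictly below this are anticipatory.
#' @param rng_seed master seed; per-stage streams are derived from it.
#' @return an object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(kernel_sd_ms = 16,
                            grid_step_ms = 1,
                            n_permutations = 10000,
                            alpha = 0.05,
                            analysis_window_ms = c(50, 300),
                            bin_edges = seq(-2.5, 2.5, length.out = 21),
                            min_horiz_amp_deg = 6,
                            max_axis_dev_deg = 4,
                            anticipatory_cut_ms = 80,
                            rng_seed = 1L) {
  stopifnot(kernel_sd_ms > 0, grid_step_ms > 0)
  if (n_permutations < 1) stop_named("bad_config", "n_permutations must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop_named("bad_config", "alpha must lie in (0,1)")
  if (!(length(analysis_window_ms) == 2 && analysis_window_ms[1] < analysis_window_ms[2])) {
    stop_named("bad_config", "analysis window start must precede end")
  }
  structure(
    list(kernel_sd_ms = kernel_sd_ms, grid_step_ms = grid_step_ms,
         n_permutations = as.integer(n_permutations), alpha = alpha,
         analysis_window_ms = as.numeric(analysis_window_ms),
         bin_edges = bin_edges,
         min_horiz_amp_deg = min_horiz_amp_deg,
         max_axis_dev_deg = max_axis_dev_deg,
         anticipatory_cut_ms = anticipatory_cut_ms,
         rng_seed = as.integer(rng_seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; unknown keys error,
#' missing keys take the defaults. Values passed in `overrides` (e.g. parsed
#' CLI flags) take precedence over the file.
#'
#' @param path YAML file path.
#' @param overrides named list overriding file values.
#' @return an `analysis_config` object.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop_named("bad_config", "unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  kernel SD        : %g ms (grid %g ms)\n", x$kernel_sd_ms, x$grid_step_ms))
  cat(sprintf("  permutations     : %d (alpha %g)\n", x$n_permutations, x$alpha))
  cat(sprintf("  analysis window  : %g..%g ms\n", x$analysis_window_ms[1], x$analysis_window_ms[2]))
  cat(sprintf("  endpoint bins    : %d on [%g, %g] deg\n",
              length(x$bin_edges) - 1L, min(x$bin_edges), max(x$bin_edges)))
  cat(sprintf("  trial filters    : horiz amp >= %g deg, axis dev <= %g deg\n",
              x$min_horiz_amp_deg, x$max_axis_dev_deg))
  cat(sprintf("  seed             : %d\n", x$rng_seed))
  invisible(x)
}
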