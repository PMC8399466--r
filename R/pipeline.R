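#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> detect/recode -> filter -> time course ->
#' mixture (Exp1-style presets) or simulate -> exploration analyses
#' (Exp2-style), writing every stage's output plus a run manifest into
#' `out_dir`. All randomness derives from `config$rng_seed`, so re-running
#' with the same configuration reproduces every output bit-exactly.
#'
#' @param out_dir run directory (created if needed).
#' @param preset `"exp1"` or `"exp2"`.
#' @param config an [analysis_config()].
#' @param n_participants,n_trials optional scale-down overrides of the
#'   preset design (defaults: 18 x 200 per condition for exp1, 24 x 512 for
#'   exp2).
#' @param stages subset of stages to run; later stages read the files
#'   earlier stages wrote, so a stage can be re-run in isolation.
#' @param traces exp2 only: also simulate raw sample streams and run the
#'   distance-to-center and heatmap analyses.
#' @param verbose print stage progress to stderr.
#' @return invisibly, the parsed report list (also written as JSON).
#' @export
run_pipeline <- function(out_dir, preset = c("exp1", "exp2"),
                         config = analysis_config(),
                         n_participants = NULL, n_trials = NULL,
                         stages = c("simulate", "analyze"),
                         traces = FALSE, verbose = TRUE) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  timing <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  trials_path <- file.path(out_dir, "trials.csv")
  events_path <- file.path(out_dir, "events.csv")
  report <- list()

  if ("simulate" %in% stages) {
    say("[simulate] preset %s", preset)
    t0 <- Sys.time()
    dat <- generate_experiment(preset, n_participants = n_participants,
                               seed = config$rng_seed, n_trials = n_trials,
                               traces = traces)
    utils::write.csv(dat$trials, trials_path, row.names = FALSE)
    write_events(dat$events, events_path)
    if (!is.null(dat$samples)) write_samples(dat$samples, file.path(out_dir, "samples.csv"))
    timing$simulate <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  if ("analyze" %in% stages) {
    t0 <- Sys.time()
    trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
    events <- read_events(events_path)
    if (preset == "exp1") {
      report <- analyze_exp1(trials, events, config, say)
    } else {
      samples <- if (traces && file.exists(file.path(out_dir, "samples.csv"))) {
        read_samples(file.path(out_dir, "samples.csv"))
      } else NULL
      report <- analyze_exp2(trials, events, samples, config, say)
    }
    timing$analyze <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }

  manifest <- list(
    preset = preset,
    config = unclass(config),
    n_participants = n_participants, n_trials = n_trials,
    package_version = as.character(utils::packageVersion("gazebias")),
    input_hashes = as.list(tools::md5sum(Filter(file.exists, c(trials_path, events_path)))),
    timing_s = timing,
    finished = format(t_start, "%Y-%m-%d %H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(report)
}

# Exp1-style analysis: per condition, recode + filter endpoints, smoothed
# one-sample cluster test against the instructed location, then the
# unimodal/bimodal model comparison restricted to the significant window.
analyze_exp1 <- function(trials, events, config, say = message) {
  out <- list()
  grid <- seq(config$analysis_window_ms[1], config$analysis_window_ms[2],
              by = config$grid_step_ms)
  for (cond in unique(trials$condition)) {
    say("[analyze] condition %s", cond)
    tr <- trials[trials$condition == cond, , drop = FALSE]
    rec <- recode_endpoints(events[events$trial_id %in% tr$trial_id, ], tr)
    flt <- filter_trials(rec, config$min_horiz_amp_deg, config$max_axis_dev_deg,
                         config$analysis_window_ms)
    kept <- flt$kept
    series <- lapply(split(kept, kept$participant_id), function(k) {
      smooth_individual(k$latency_ms, k$endpoint_rel_deg,
                        kernel_sd_ms = config$kernel_sd_ms, grid_ms = grid,
                        participant_id = k$participant_id[1])
    })
    ct <- cluster_test_onesample(series, baseline = 0,
                                 window_ms = config$analysis_window_ms,
                                 n_perm = config$n_permutations,
                                 alpha = config$alpha,
                                 seed = derive_seed(config$rng_seed, paste0("ct_", cond)))
    win <- if (!is.na(ct$window_ms[1])) ct$window_ms else config$analysis_window_ms
    mix <- compare_endpoint_models(kept, window_ms = win, edges = config$bin_edges,
                                   seed = derive_seed(config$rng_seed, paste0("mx_", cond)))
    gc_ <- group_comparison(mix$w_single, mix$w_dual)
    out[[cond]] <- list(
      filter_report = flt$report,
      timecourse = list(p = ct$p, t = ct$t_obs, t_crit = ct$t_crit,
                        window_ms = ct$window_ms),
      mixture = list(n_favoring_single = gc_$n_favoring_single,
                     n_favoring_dual = gc_$n_favoring_dual,
                     Z = gc_$Z, p = gc_$p,
                     mean_w_single = mean(mix$w_single))
    )
  }
  out
}

# Exp2-style analysis from events (plus, optionally, raw samples): latency
# and fixation-duration ANOVAs, anticipatory-frequency tests, saccade rate,
# exploration metrics, endpoint mean/variability ANOVAs; with samples also
# the distance-to-center time courses and heatmaps.
analyze_exp2 <- function(trials, events, samples, config, say = message) {
  say("[analyze] exploration analyses")
  prim <- events[events$index_in_trial == 1L, ]
  m <- match(prim$trial_id, trials$trial_id)
  prim <- cbind(prim, trials[m, c("participant_id", "object_present", "contrast")])
  prim$anticipatory <- prim$latency_ms < config$anticipatory_cut_ms

  # fixation duration between primary and secondary saccade
  sec <- events[events$index_in_trial == 2L, ]
  ms <- match(sec$trial_id, prim$trial_id)
  fixdur <- sec$onset_ms - prim$offset_ms[ms]

  reg <- prim[!prim$anticipatory, ]
  lat_cells <- stats::aggregate(reg$latency_ms,
    list(participant_id = reg$participant_id,
         object = ifelse(reg$object_present, "present", "absent"),
         contrast = reg$contrast), mean)
  names(lat_cells)[4] <- "value"
  ok <- !is.na(ms)
  fd <- data.frame(prim[ms[ok], ], value = fixdur[ok])
  fd <- fd[!fd$anticipatory, ]
  fd_cells <- stats::aggregate(fd$value,
    list(participant_id = fd$participant_id,
         object = ifelse(fd$object_present, "present", "absent"),
         contrast = fd$contrast), mean)
  names(fd_cells)[4] <- "value"

  ant_frac <- stats::aggregate(prim$anticipatory,
    list(participant_id = prim$participant_id,
         object = ifelse(prim$object_present, "present", "absent"),
         contrast = prim$contrast), mean)

  rate <- saccade_rate(events, trials$trial_id)
  expl <- exploration_metrics(events, trials$trial_id)

  later <- events[events$index_in_trial %in% 2:5, ]
  ml <- match(later$trial_id, trials$trial_id)
  ecells <- endpoint_cell_stats(data.frame(
    participant_id = trials$participant_id[ml],
    object = ifelse(trials$object_present[ml], "present", "absent"),
    contrast = trials$contrast[ml],
    saccade_number = later$index_in_trial,
    endpoint_x = later$x1, endpoint_y = later$y1,
    stringsAsFactors = FALSE))
  ean <- endpoint_anova(ecells)

  flatten_anova <- function(a) {
    if (a$degenerate) return(list(degenerate = TRUE))
    lapply(split(a$effects, a$effects$effect), function(r) {
      list(F = r$F, df1 = r$df1, df2 = r$df2, p = r$p_report, significant = r$significant)
    })
  }
  out <- list(
    latency_anova = flatten_anova(latency_anova(lat_cells)),
    fixation_duration_anova = flatten_anova(latency_anova(fd_cells)),
    anticipatory_fraction = mean(prim$anticipatory),
    mean_latency_ms = stats::setNames(
      as.list(tapply(reg$latency_ms, ifelse(reg$object_present, "present", "absent"), mean)),
      c("absent", "present")),
    saccade_rate_mean = mean(rate$rate),
    exploration = list(mean_amplitude_deg = mean(expl$mean_amplitude_deg, na.rm = TRUE),
                       mean_saccades_per_trial = mean(expl$mean_saccades_per_trial)),
    endpoint_anova = lapply(ean[c("mean_x", "mean_y", "sd_x", "sd_y")], flatten_anova)
  )
  if (!is.null(samples)) {
    dt <- distance_timecourse(samples, trials)
    out$distance_conditions <- names(dt$series)
  }
  out
}
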