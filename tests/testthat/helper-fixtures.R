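# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# Minimal smoothed-series builder on a common grid.
make_series <- function(lat, val, grid = 50:300, sd = 16, pid = "p") {
  smooth_individual(lat, val, kernel_sd_ms = sd, grid_ms = grid, participant_id = pid)
}

# N participants of pure-noise endpoint data smoothed onto the grid.
null_series <- function(n_participants = 18, n_trials = 200, sd_noise = 0.7,
                        grid = 50:300, seed = 1) {
  lapply(seq_len(n_participants), function(p) {
    set.seed(seed * 1000 + p)
    lat <- rnorm(n_trials, 110, 20) + rexp(n_trials, 1 / 40)
    make_series(lat, rnorm(n_trials, 0, sd_noise), grid = grid, pid = p)
  })
}

# A small trial table with matching primary-saccade events, hand-laid-out.
make_trials_events <- function(endpoints_y, signs, goal = c(12, 0),
                               latency = 150, mirrored = FALSE, axis = "y") {
  n <- length(endpoints_y)
  trials <- data.frame(
    trial_id = sprintf("t%03d", seq_len(n)),
    condition = "look_center", axis = axis,
    displacement_sign = signs,
    mirrored = rep_len(mirrored, n),
    goal_x = goal[1], goal_y = goal[2],
    attractor_x = goal[1] + if (axis == "x") signs * 2 else 0,
    attractor_y = goal[2] + if (axis == "y") signs * 2 else 0,
    stringsAsFactors = FALSE
  )
  events <- data.frame(
    trial_id = trials$trial_id, index_in_trial = 1L,
    onset_ms = rep_len(latency, n), offset_ms = rep_len(latency, n) + 40,
    x0 = 0, y0 = 0,
    x1 = if (axis == "x") endpoints_y else goal[1],
    y1 = if (axis == "y") endpoints_y else goal[2],
    stringsAsFactors = FALSE
  )
  events$amplitude_deg <- sqrt((events$x1 - events$x0)^2 + (events$y1 - events$y0)^2)
  events$latency_ms <- events$onset_ms
  list(trials = trials, events = events)
}
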