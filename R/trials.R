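#' Trial design tables
#'
#' A trial table is a plain data.frame with one row per trial and at least:
#' \describe{
#'   \item{`trial_id`}{unique identifier.}
#'   \item{`condition`}{one of `look_center`, `look_object`, `look_cue`,
#'     `explore`.}
#'   \item{`axis`}{the analysis axis, `"y"` (vertical, Exp1-style) or `"x"`
#'     (horizontal, Exp2-style): the axis on which goal and attractor differ.}
#'   \item{`displacement_sign`}{+1 / -1, direction of the attractor
#'     displacement on the analysis axis.}
#'   \item{`mirrored`}{logical; horizontal mirroring of the image.}
#'   \item{`goal_x, goal_y`}{instructed location (deg, screen-centered).}
#'   \item{`attractor_x, attractor_y`}{competing location (deg).}
#' }
#' Optional columns (`object_present`, `contrast`, `center_x`, `center_y`,
#' `participant_id`, ...) are carried through untouched.
#'
#' @param trials candidate data.frame.
#' @return the validated data.frame.
#' @export
validate_trials <- function(trials) {
  need <- c("trial_id", "condition", "axis", "displacement_sign", "mirrored",
            "goal_x", "goal_y", "attractor_x", "attractor_y")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop_named("bad_trials", "trial table lacks columns: %s",
                               paste(miss, collapse = ", "))
  if (anyDuplicated(trials$trial_id)) stop_named("bad_trials", "duplicate trial_id")
  if (!all(trials$axis %in% c("x", "y"))) stop_named("bad_trials", "axis must be 'x' or 'y'")
  if (!all(trials$displacement_sign %in% c(-1, 1))) {
    stop_named("bad_trials", "displacement_sign must be +1 or -1")
  }
  trials
}

#' Recode saccade endpoints onto the analysis axis
#'
#' Takes the saccade of ordinal `which_saccade` in each trial, projects its
#' endpoint onto the trial's analysis axis relative to the instructed
#' location, and re-signs it so that the direction of the attractor
#' displacement is positive. Mirroring flips the sign on the horizontal axis
#' only. After recoding, positive values always point toward the attractor
#' (the salient object, or the image center, depending on condition), so
#' biases pool across displacement directions and mirror versions.
#'
#' @param events event table (see [read_events()]), onsets referenced to
#'   image onset.
#' @param trials validated trial table.
#' @param which_saccade ordinal of the saccade to recode (1 = primary).
#' @return data.frame `trial_id, latency_ms, endpoint_rel_deg, endpoint_x,
#'   endpoint_y, axis_raw_deg, horiz_amp_deg` (the latter two feed the trial
#'   filters). Trials lacking the requested saccade are excluded and listed
#'   in the `excluded` attribute.
#' @export
recode_endpoints <- function(events, trials, which_saccade = 1L) {
  trials <- validate_trials(trials)
  ev <- events[events$index_in_trial == which_saccade, , drop = FALSE]
  idx <- match(trials$trial_id, ev$trial_id)
  has <- !is.na(idx)
  excluded <- trials$trial_id[!has]
  tr <- trials[has, , drop = FALSE]
  ev <- ev[idx[has], , drop = FALSE]

  on_x <- tr$axis == "x"
  raw <- ifelse(on_x, ev$x1, ev$y1)
  goal <- ifelse(on_x, tr$goal_x, tr$goal_y)
  # mirroring affects only the horizontal axis
  mirror_sign <- ifelse(on_x & tr$mirrored, -1, 1)
  rel <- tr$displacement_sign * mirror_sign * (raw - goal)

  out <- data.frame(
    trial_id = tr$trial_id,
    latency_ms = ev$latency_ms,
    endpoint_rel_deg = rel,
    endpoint_x = ev$x1,
    endpoint_y = ev$y1,
    axis_raw_deg = raw,
    horiz_amp_deg = abs(ev$x1 - ev$x0),
    stringsAsFactors = FALSE
  )
  if ("participant_id" %in% names(tr)) out$participant_id <- tr$participant_id
  if ("condition" %in% names(tr)) out$condition <- tr$condition
  attr(out, "excluded") <- excluded
  rownames(out) <- NULL
  out
}

#' Filter recoded trials
#'
#' Applies the endpoint-quality rules: discard trials whose saccade has a
#' horizontal amplitude below `min_horiz_amp_deg` (default 6 deg) or whose
#' endpoint on the analysis axis deviates more than `max_axis_dev_deg`
#' (default 4 deg, strictly) from the screen midline, and keep only trials
#' whose latency falls inside the analysis window.
#'
#' @param endpoints output of [recode_endpoints()].
#' @param min_horiz_amp_deg amplitude rule threshold (deg).
#' @param max_axis_dev_deg midline-deviation rule threshold (deg).
#' @param window_ms length-2 latency window (ms), inclusive.
#' @return list with `kept` (filtered endpoint table) and `report` (counts
#'   removed per rule, applied in the order amplitude, deviation, window, and
#'   the fraction of amplitude/deviation-clean trials inside the window).
#' @export
filter_trials <- function(endpoints, min_horiz_amp_deg = 6,
                          max_axis_dev_deg = 4, window_ms = c(50, 300)) {
  stopifnot(min_horiz_amp_deg > 0, max_axis_dev_deg > 0)
  n0 <- nrow(endpoints)
  bad_amp <- endpoints$horiz_amp_deg < min_horiz_amp_deg
  bad_dev <- !bad_amp & abs(endpoints$axis_raw_deg) > max_axis_dev_deg
  clean <- !(bad_amp | bad_dev)
  in_win <- endpoints$latency_ms >= window_ms[1] & endpoints$latency_ms <= window_ms[2]
  kept <- endpoints[clean & in_win, , drop = FALSE]
  if (nrow(kept) == 0L) stop_named("empty_selection", "no trials survive the filters")
  rownames(kept) <- NULL
  list(
    kept = kept,
    report = list(
      n_input = n0,
      removed_amplitude = sum(bad_amp),
      removed_deviation = sum(bad_dev),
      removed_window = sum(clean & !in_win),
      n_kept = nrow(kept),
      fraction_in_window = if (sum(clean)) mean(in_win[clean]) else NA_real_
    )
  )
}
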