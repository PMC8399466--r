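#' Saccade detector parameters
#'
#' Thresholds follow the standard velocity/acceleration/displacement parsing
#' convention for 1 kHz video-oculography: a sample is saccadic when its
#' speed exceeds 30 deg/s or its acceleration magnitude exceeds
#' 8000 deg/s^2, and candidate events must displace gaze by at least
#' 0.15 deg. The vendor parser's internals are not public; here velocity is
#' a 5-point Savitzky-Golay local derivative of position and acceleration
#' the same derivative of the smoothed speed, which makes the thresholds
#' meaningful at 1 kHz. `min_duration_ms` and `merge_gap_ms` are parsing
#' conventions, not study-reported values.
#'
#' @param vel_thresh velocity threshold, deg/s.
#' @param acc_thresh acceleration threshold, deg/s^2.
#' @param disp_thresh minimum net displacement of an event, deg.
#' @param min_duration_ms minimum event duration, ms.
#' @param merge_gap_ms events closer than this are merged, ms.
#' @return object of class `detector_params`.
#' @export
detector_params <- function(vel_thresh = 30, acc_thresh = 8000,
                            disp_thresh = 0.15, min_duration_ms = 4,
                            merge_gap_ms = 20) {
  stopifnot(vel_thresh > 0, acc_thresh > 0, disp_thresh > 0,
            min_duration_ms > 0, merge_gap_ms > 0)
  structure(list(vel_thresh = vel_thresh, acc_thresh = acc_thresh,
                 disp_thresh = disp_thresh, min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms),
            class = "detector_params")
}

# 5-point Savitzky-Golay first derivative (quadratic), per second.
sg_deriv <- function(x, dt_s) {
  if (length(x) < 5) stop_named("short_stream", "need >= 5 samples")
  signal::sgolayfilt(x, p = 2, n = 5, m = 1, ts = dt_s)
}

#' Detect saccades in a gaze sample stream
#'
#' Marks samples whose speed or acceleration exceeds threshold, turns
#' maximal saccadic runs longer than `min_duration_ms` with net displacement
#' of at least `disp_thresh` into events, and merges events separated by
#' less than `merge_gap_ms`. Events are returned in temporal order and
#' indexed; events starting before image onset (`onset_ms <= 0`) get index
#' 0 so that index 1 is the primary post-onset saccade.
#'
#' @param samples data.frame `t_ms,x_deg,y_deg` for one trial (a `trial_id`
#'   column is carried through if present).
#' @param params a [detector_params()].
#' @return event data.frame as in [read_events()]; zero rows when nothing
#'   exceeds threshold.
#' @export
detect_saccades <- function(samples, params = detector_params()) {
  n <- nrow(samples)
  if (n < 5) stop_named("short_stream", "stream too short for detection (%d samples)", n)
  t <- samples$t_ms
  dt_s <- stats::median(diff(t)) / 1000
  vx <- sg_deriv(samples$x_deg, dt_s)
  vy <- sg_deriv(samples$y_deg, dt_s)
  speed <- sqrt(vx^2 + vy^2)
  acc <- sg_deriv(speed, dt_s)
  hot <- speed > params$vel_thresh | abs(acc) > params$acc_thresh

  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(seg)) {
    dur <- t[seg$end] - t[seg$start]
    seg <- seg[dur > params$min_duration_ms, , drop = FALSE]
  }
  if (nrow(seg)) {
    disp <- sqrt((samples$x_deg[seg$end] - samples$x_deg[seg$start])^2 +
                 (samples$y_deg[seg$end] - samples$y_deg[seg$start])^2)
    seg <- seg[disp >= params$disp_thresh, , drop = FALSE]
  }
  # merge events separated by short gaps
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      gap <- t[seg$start[i]] - t[merged$end[nrow(merged)]]
      if (gap < params$merge_gap_ms) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, , drop = FALSE])
      }
    }
    seg <- merged
  }
  if (!nrow(seg)) {
    out <- data.frame(trial_id = character(), index_in_trial = integer(),
                      onset_ms = numeric(), offset_ms = numeric(),
                      x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
                      stringsAsFactors = FALSE)
    return(as_events(out))
  }
  out <- data.frame(
    trial_id = if ("trial_id" %in% names(samples)) samples$trial_id[seg$start] else NA_character_,
    onset_ms = t[seg$start], offset_ms = t[seg$end],
    x0 = samples$x_deg[seg$start], y0 = samples$y_deg[seg$start],
    x1 = samples$x_deg[seg$end], y1 = samples$y_deg[seg$end],
    stringsAsFactors = FALSE
  )
  post <- out$onset_ms > 0
  out$index_in_trial <- 0L
  out$index_in_trial[post] <- seq_len(sum(post))
  out <- out[c("trial_id", "index_in_trial", "onset_ms", "offset_ms",
               "x0", "y0", "x1", "y1")]
  as_events(out)
}

#' Detect saccades for every trial in a sample table
#'
#' @param samples multi-trial sample table (`trial_id` column required).
#' @inheritParams detect_saccades
#' @return combined event table.
#' @export
detect_saccades_by_trial <- function(samples, params = detector_params()) {
  parts <- lapply(split(samples, samples$trial_id), function(s) {
    s <- s[order(s$t_ms), , drop = FALSE]
    detect_saccades(s, params)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Split events into anticipatory and regular saccades
#'
#' A saccade counts as anticipatory when its latency is strictly below the
#' cut (80 ms by default): it is initiated before the image can have been
#' processed. A latency of exactly 80 ms is regular.
#'
#' @param events event table with `latency_ms`.
#' @param latency_cut_ms classification boundary (ms).
#' @return list with `anticipatory` and `regular` event tables (disjoint,
#'   jointly exhaustive).
#' @export
classify_anticipatory <- function(events, latency_cut_ms = 80) {
  ant <- events$latency_ms < latency_cut_ms
  list(anticipatory = events[ant, , drop = FALSE],
       regular = events[!ant, , drop = FALSE])
}
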