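#' Read gaze samples
#'
#' Reads time-stamped 2-D gaze positions, grouped by trial and re-referenced
#' so that `t_ms = 0` at image onset. Positions are screen-centered degrees
#' of visual angle, x positive rightward, y positive upward; the nominal
#' sampling interval is 1 ms (gaps are allowed and flagged).
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`plain_table`}{UTF-8 CSV with mandatory header
#'     `trial_id,t_ms,x_deg,y_deg`, already referenced to image onset.}
#'   \item{`asc_minimal`}{a minimal EyeLink-ASC-like stream: sample lines
#'     `<timestamp> <x> <y> <pupil>` plus `MSG <timestamp> TRIALID <id>`
#'     lines opening a trial and `MSG <timestamp> IMGONSET` (or `SYNCTIME`)
#'     lines marking image onset. Everything else is ignored. Coordinates
#'     are taken as degrees as-is; the full vendor grammar is out of scope.}
#' }
#'
#' @param path input file.
#' @param dialect `"plain_table"` or `"asc_minimal"`.
#' @return a data.frame with columns `trial_id, t_ms, x_deg, y_deg`, sorted
#'   by trial and time. Attributes: `n_malformed` (count of unparseable
#'   lines) and `rejected` (data.frame of trials dropped for a missing onset
#'   marker, with a reason column).
#' @export
read_samples <- function(path, dialect = c("plain_table", "asc_minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_named("missing_file", "no such file: %s", path)
  if (dialect == "plain_table") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("trial_id", "t_ms", "x_deg", "y_deg")
    if (!all(need %in% names(df))) {
      stop_named("bad_header", "plain_table requires columns %s", paste(need, collapse = ","))
    }
    df <- df[need]
    check_monotonic(df)   # in file order: rows of a trial must be in time order
    df <- df[order(match(df$trial_id, unique(df$trial_id)), df$t_ms), ]
    attr(df, "n_malformed") <- 0L
    attr(df, "rejected") <- empty_rejects()
    rownames(df) <- NULL
    return(df)
  }
  parse_asc_minimal(readLines(path, warn = FALSE))
}

check_monotonic <- function(df) {
  bad <- tapply(df$t_ms, df$trial_id, function(t) any(diff(t) <= 0))
  if (any(unlist(bad))) {
    stop_named("non_monotonic", "non-monotonic timestamps in trial(s): %s",
               paste(names(bad)[unlist(bad)], collapse = ", "))
  }
  invisible(df)
}

empty_rejects <- function() {
  data.frame(trial_id = character(), reason = character(), stringsAsFactors = FALSE)
}

parse_asc_minimal <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_msg <- startsWith(lines, "MSG")
  out <- list(); rejected <- list(); n_malformed <- 0L
  cur_id <- NULL; cur_onset <- NA_real_; cur_t <- c(); cur_x <- c(); cur_y <- c()
  flush <- function() {
    if (is.null(cur_id)) return()
    if (is.na(cur_onset)) {
      rejected[[length(rejected) + 1L]] <<- data.frame(
        trial_id = cur_id, reason = "missing onset marker", stringsAsFactors = FALSE)
    } else if (length(cur_t)) {
      t_ms <- cur_t - cur_onset
      if (any(diff(t_ms) <= 0)) {
        stop_named("non_monotonic", "non-monotonic timestamps in trial %s", cur_id)
      }
      out[[length(out) + 1L]] <<- data.frame(
        trial_id = cur_id, t_ms = t_ms, x_deg = cur_x, y_deg = cur_y,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (is_msg[i]) {
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) >= 3 && f[3] == "TRIALID") {
        flush()
        cur_id <- if (length(f) >= 4) f[4] else as.character(length(out) + 1L)
        cur_onset <- NA_real_; cur_t <- c(); cur_x <- c(); cur_y <- c()
      } else if (length(f) >= 3 && f[3] %in% c("IMGONSET", "SYNCTIME")) {
        cur_onset <- suppressWarnings(as.numeric(f[2]))
      }
      next
    }
    f <- strsplit(ln, "[ \t]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 3 || anyNA(v[1:3])) { n_malformed <- n_malformed + 1L; next }
    if (is.null(cur_id)) { n_malformed <- n_malformed + 1L; next }
    cur_t <- c(cur_t, v[1]); cur_x <- c(cur_x, v[2]); cur_y <- c(cur_y, v[3])
  }
  flush()
  df <- if (length(out)) do.call(rbind, out) else {
    data.frame(trial_id = character(), t_ms = numeric(),
               x_deg = numeric(), y_deg = numeric(), stringsAsFactors = FALSE)
  }
  attr(df, "n_malformed") <- n_malformed
  attr(df, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else empty_rejects()
  rownames(df) <- NULL
  df
}

#' Write gaze samples as a plain_table CSV
#'
#' Inverse of [read_samples()] for the `plain_table` dialect; round-trips
#' every sample exactly (values are written with full precision).
#'
#' @param samples data.frame `trial_id,t_ms,x_deg,y_deg`.
#' @param path output file.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(format(samples, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write saccade event tables
#'
#' Event tables are UTF-8 CSV with the mandatory header
#' `trial_id,index_in_trial,onset_ms,offset_ms,x0,y0,x1,y1`. Amplitude and
#' latency are recomputed on read: amplitude is the Euclidean start-to-end
#' displacement; latency equals `onset_ms` (onsets are referenced to image
#' onset).
#'
#' @param path CSV path.
#' @return data.frame of events with `amplitude_deg` and `latency_ms` added.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "index_in_trial", "onset_ms", "offset_ms", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(df))) {
    stop_named("bad_header", "event table requires columns %s", paste(need, collapse = ","))
  }
  as_events(df[need])
}

#' @rdname read_events
#' @param events event data.frame.
#' @export
write_events <- function(events, path) {
  keep <- c("trial_id", "index_in_trial", "onset_ms", "offset_ms", "x0", "y0", "x1", "y1")
  utils::write.csv(format(events[keep], digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical event table: recompute amplitude/latency, enforce offset > onset.
as_events <- function(df) {
  if (nrow(df) && any(df$offset_ms <= df$onset_ms)) {
    stop_named("bad_event", "event offset must exceed onset")
  }
  df$amplitude_deg <- sqrt((df$x1 - df$x0)^2 + (df$y1 - df$y0)^2)
  df$latency_ms <- df$onset_ms
  rownames(df) <- NULL
  df
}
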