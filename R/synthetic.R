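#' Latency-dependent bias window
#'
#' The attractor's pull on saccade endpoints is modelled as a Gaussian
#' window over saccade latency, w(t) = A exp(-(t - t_peak)^2 / (2 sd^2)):
#' involuntary biases are absent for the earliest responses, peak for
#' saccades initiated roughly 100-300 ms after stimulus onset, and decay as
#' voluntary control takes over. A two-parameter symmetric profile is the
#' simplest shape consistent with reported bias windows; an asymmetric
#' rise/decay would be a straightforward extension.
#'
#' @param amplitude peak bias weight A in [0, 1].
#' @param t_peak_ms latency of maximum bias (ms).
#' @param width_ms Gaussian SD of the window (ms).
#' @return function w(t) mapping latencies to weights in [0, A].
#' @export
bias_profile <- function(amplitude = 0.75, t_peak_ms = 150, width_ms = 50) {
  stopifnot(amplitude >= 0, amplitude <= 1, width_ms > 0)
  function(t) amplitude * exp(-(t - t_peak_ms)^2 / (2 * width_ms^2))
}

#' Generator parameters for endpoint trials
#'
#' The latency model is ex-Gaussian (normal mu/sigma plus exponential tau;
#' defaults put the latency mass inside the 50-300 ms analysis window) or,
#' with `inhibition = TRUE`, a two-component ex-Gaussian mixture whose gap
#' emulates the saccadic-inhibition dip that produces bimodal latency
#' distributions in gap/cue paradigms. Endpoints combine an instructed goal
#' location and a competing attractor under the latency-dependent window w:
#' in `bias` mode every endpoint shifts continuously,
#'   endpoint = (1 - w) goal + w attractor + noise,
#' in `capture` mode a fraction w of trials goes to the attractor outright,
#'   endpoint ~ N(attractor) with probability w, else N(goal).
#' Both modes share the mean time course; capture adds w(1-w) d^2 of
#' variance at mid-latencies (law of total variance), which is what the
#' unimodal/bimodal model comparison detects. Motor noise is isotropic
#' Gaussian per axis.
#'
#' @param mode `"bias"` or `"capture"`.
#' @param n_trials trials per participant (200 = one Exp1-style block).
#' @param goal_deg instructed 2-D location (deg).
#' @param separation_deg goal-to-attractor distance d on the analysis axis.
#' @param axis analysis axis, `"y"` (Exp1-style) or `"x"`.
#' @param profile a [bias_profile()].
#' @param sigma_m motor noise SD per axis (deg).
#' @param latency_mu,latency_sigma,latency_tau ex-Gaussian parameters (ms).
#' @param inhibition if TRUE, mix an early component and a post-dip
#'   component to yield a bimodal latency distribution.
#' @return list of class `generator_params`.
#' @export
generator_params <- function(mode = c("bias", "capture"), n_trials = 200,
                             goal_deg = c(12, 0), separation_deg = 2,
                             axis = "y",
                             profile = bias_profile(),
                             sigma_m = 0.7,
                             latency_mu = 110, latency_sigma = 20,
                             latency_tau = 40, inhibition = FALSE) {
  mode <- match.arg(mode)
  stopifnot(sigma_m > 0, latency_sigma > 0, latency_tau > 0, separation_deg > 0)
  structure(list(mode = mode, n_trials = as.integer(n_trials),
                 goal_deg = goal_deg, separation_deg = separation_deg,
                 axis = axis, profile = profile, sigma_m = sigma_m,
                 latency_mu = latency_mu, latency_sigma = latency_sigma,
                 latency_tau = latency_tau, inhibition = inhibition),
            class = "generator_params")
}

r_exgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, 1 / tau)
}

sample_latencies <- function(params, n) {
  if (!params$inhibition) {
    return(r_exgauss(n, params$latency_mu, params$latency_sigma, params$latency_tau))
  }
  # early component before the inhibition dip, late component after it
  early <- stats::runif(n) < 0.35
  ifelse(early,
         r_exgauss(n, params$latency_mu - 60, params$latency_sigma * 0.6, 15),
         r_exgauss(n, params$latency_mu + 60, params$latency_sigma, params$latency_tau))
}

#' Generate one participant's endpoint trials
#'
#' Produces a trial design table (balanced attractor displacement signs),
#' the matching primary-saccade event table, and the generating truth. The
#' dataset feeds [recode_endpoints()] and everything downstream, and is a
#' pure function of (params, seed).
#'
#' @param params a [generator_params()].
#' @param seed RNG seed.
#' @param participant_id id carried into the tables.
#' @param condition condition label for the trial table.
#' @return list `trials` (design table), `events` (primary saccades),
#'   `truth` (latencies and bias weights per trial).
#' @export
generate_endpoint_trials <- function(params, seed = 1L, participant_id = "p01",
                                     condition = "look_center") {
  with_seed(seed, {
    n <- params$n_trials
    sign <- rep(c(1, -1), length.out = n)
    lat <- sample_latencies(params, n)
    w <- params$profile(lat)
    d <- params$separation_deg
    gx <- params$goal_deg[1]; gy <- params$goal_deg[2]
    ax <- if (params$axis == "x") sign * d else 0
    ay <- if (params$axis == "y") sign * d else 0
    if (params$mode == "bias") {
      ex <- gx + w * ax + stats::rnorm(n, 0, params$sigma_m)
      ey <- gy + w * ay + stats::rnorm(n, 0, params$sigma_m)
    } else {
      cap <- stats::runif(n) < w
      ex <- gx + ifelse(cap, ax, 0) + stats::rnorm(n, 0, params$sigma_m)
      ey <- gy + ifelse(cap, ay, 0) + stats::rnorm(n, 0, params$sigma_m)
    }
    trial_id <- sprintf("%s_t%04d", participant_id, seq_len(n))
    trials <- data.frame(
      trial_id = trial_id, participant_id = participant_id,
      condition = condition, axis = params$axis,
      displacement_sign = sign, mirrored = FALSE,
      goal_x = gx, goal_y = gy,
      attractor_x = gx + ax, attractor_y = gy + ay,
      stringsAsFactors = FALSE
    )
    amp <- sqrt(ex^2 + ey^2)
    events <- as_events(data.frame(
      trial_id = trial_id, index_in_trial = 1L,
      onset_ms = lat, offset_ms = lat + 2.2 * amp + 21,
      x0 = 0, y0 = 0, x1 = ex, y1 = ey, stringsAsFactors = FALSE
    ))
    list(trials = trials, events = events,
         truth = list(latency_ms = lat, w = w, params = params))
  })
}

#' Synthesize a 1 kHz gaze trace from a fixation sequence
#'
#' Holds each fixation position for its duration and moves between
#' fixations with a minimum-jerk position profile whose duration follows
#' the main sequence D = 2.2 ms/deg x amplitude + 21 ms (standard
#' literature constants). Additive isotropic Gaussian sample noise on top.
#' The ground-truth event list is returned alongside, which makes the trace
#' the substrate for validating the saccade detector and the distance
#' analyses.
#'
#' @param fixations data.frame `x_deg, y_deg, duration_ms` in order.
#' @param sample_noise_sd per-sample position noise SD (deg).
#' @param seed RNG seed.
#' @param t0_ms time of the first sample (ms).
#' @param trial_id id stamped on samples and events.
#' @return list `samples` (t_ms,x_deg,y_deg), `events` (ground truth).
#' @export
generate_gaze_trace <- function(fixations, sample_noise_sd = 0.02, seed = 1L,
                                t0_ms = 0, trial_id = "t0001") {
  stopifnot(nrow(fixations) >= 1, all(fixations$duration_ms > 0))
  nf <- nrow(fixations)
  x <- c(); y <- c()
  truth <- list()
  for (i in seq_len(nf)) {
    hold <- round(fixations$duration_ms[i])
    x <- c(x, rep(fixations$x_deg[i], hold))
    y <- c(y, rep(fixations$y_deg[i], hold))
    if (i < nf) {
      dx <- fixations$x_deg[i + 1] - fixations$x_deg[i]
      dy <- fixations$y_deg[i + 1] - fixations$y_deg[i]
      amp <- sqrt(dx^2 + dy^2)
      dur <- max(round(2.2 * amp + 21), 2)
      tau <- seq_len(dur) / dur
      s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5   # minimum jerk
      onset <- t0_ms + length(x)
      x <- c(x, fixations$x_deg[i] + dx * s)
      y <- c(y, fixations$y_deg[i] + dy * s)
      truth[[length(truth) + 1L]] <- data.frame(
        trial_id = trial_id, index_in_trial = NA_integer_,
        onset_ms = onset, offset_ms = onset + dur,
        x0 = fixations$x_deg[i], y0 = fixations$y_deg[i],
        x1 = fixations$x_deg[i + 1], y1 = fixations$y_deg[i + 1],
        stringsAsFactors = FALSE)
    }
  }
  nT <- length(x)
  samples <- with_seed(seed, data.frame(
    trial_id = trial_id,
    t_ms = t0_ms + seq_len(nT) - 1,
    x_deg = x + stats::rnorm(nT, 0, sample_noise_sd),
    y_deg = y + stats::rnorm(nT, 0, sample_noise_sd),
    stringsAsFactors = FALSE
  ))
  events <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(events)) {
    post <- events$onset_ms > 0
    events$index_in_trial <- 0L
    events$index_in_trial[post] <- seq_len(sum(post))
    events <- as_events(events)
  }
  list(samples = samples, events = events)
}

# Ground-truth event table implied by a fixation schedule, using the same
# rounding and main-sequence arithmetic as generate_gaze_trace (so the two
# agree exactly), without synthesizing samples.
schedule_events <- function(fixations, t0_ms = 0, trial_id = "t0001") {
  nf <- nrow(fixations)
  if (nf < 2) return(NULL)
  truth <- vector("list", nf - 1L)
  t <- t0_ms
  for (i in seq_len(nf - 1L)) {
    t <- t + round(fixations$duration_ms[i])
    dx <- fixations$x_deg[i + 1] - fixations$x_deg[i]
    dy <- fixations$y_deg[i + 1] - fixations$y_deg[i]
    amp <- sqrt(dx^2 + dy^2)
    dur <- max(round(2.2 * amp + 21), 2)
    truth[[i]] <- data.frame(
      trial_id = trial_id, index_in_trial = NA_integer_,
      onset_ms = t, offset_ms = t + dur,
      x0 = fixations$x_deg[i], y0 = fixations$y_deg[i],
      x1 = fixations$x_deg[i + 1], y1 = fixations$y_deg[i + 1],
      stringsAsFactors = FALSE)
    t <- t + dur
  }
  events <- do.call(rbind, truth)
  post <- events$onset_ms > 0
  events$index_in_trial <- 0L
  events$index_in_trial[post] <- seq_len(sum(post))
  as_events(events)
}

# Exp2-style scanpath schedule for one exploration trial: primary saccade
# to the image after an ex-Gaussian (or anticipatory) latency, a first
# fixation, then exploration fixations sampled from an attractor mixture
# (object / image center vs. uniform over the image). Durations in ms.
# Defaults emulate the study's printed summary statistics: ~12.9%
# anticipatory saccades, mean regular latencies 149.7 (object present) /
# 133.5 ms (absent), first fixation durations 226.5 / 183.1 ms, about five
# >= 1 deg saccades per trial at a mid-trial saccadic-sample rate near 0.1,
# mean amplitude near 6.4 deg. A low image-monitor contrast widens the
# horizontal scatter of exploration targets (`low_contrast_x_scale`),
# emulating the reduced consistency of endpoint selection.
scanpath_defaults <- function() {
  list(
    p_anticipatory = c(present_low = 0.139, present_high = 0.120,
                       absent_low = 0.143, absent_high = 0.113),
    latency_mu = c(present = 109.7, absent = 93.5),
    latency_sigma = 20, latency_tau = 40,
    anticipatory_mean = 55, anticipatory_sd = 12,
    first_fix_mean = c(present = 226.5, absent = 183.1), first_fix_shape = 8,
    fix_mean = 300, fix_shape = 6,
    p_micro = 0.3, micro_amp = c(0.2, 0.8),
    attractor_weight = 0.75, attractor_sd = 2.2, uniform_span = 0.5,
    low_contrast_x_scale = 1.6,
    image_deg = c(23.5, 21.1),
    trial_dur_ms = 2000,
    endpoint_sd = 1.0
  )
}

#' Generate one Exp2-style exploration trial
#'
#' @param object_present logical.
#' @param contrast `"low"` or `"high"`.
#' @param image_center_deg 2-D image center (deg, screen-centered).
#' @param object_deg 2-D object center (ignored when absent).
#' @param fix_start_deg initial fixation position.
#' @param opts scanpath options, see `scanpath_defaults()` internals.
#' @param seed RNG seed.
#' @return list `fixations` (schedule incl. the initial fixation),
#'   `anticipatory` (logical), `latency_ms`.
#' @export
generate_exploration_trial <- function(object_present, contrast,
                                       image_center_deg, object_deg,
                                       fix_start_deg = c(0, 11),
                                       opts = scanpath_defaults(), seed = 1L) {
  with_seed(seed, {
    key <- paste0(if (object_present) "present" else "absent", "_", contrast)
    anticipatory <- stats::runif(1) < opts$p_anticipatory[[key]]
    lat <- if (anticipatory) {
      max(stats::rnorm(1, opts$anticipatory_mean, opts$anticipatory_sd), 20)
    } else {
      mu <- opts$latency_mu[[if (object_present) "present" else "absent"]]
      max(r_exgauss(1, mu, opts$latency_sigma, opts$latency_tau), 81)
    }
    target <- if (anticipatory) c(0, 0) else if (object_present) object_deg else image_center_deg
    primary <- target + stats::rnorm(2, 0, opts$endpoint_sd)
    ff_mean <- opts$first_fix_mean[[if (object_present) "present" else "absent"]]
    first_fix <- stats::rgamma(1, opts$first_fix_shape, opts$first_fix_shape / ff_mean)
    fx <- data.frame(x_deg = c(fix_start_deg[1], primary[1]),
                     y_deg = c(fix_start_deg[2], primary[2]),
                     duration_ms = c(lat, first_fix))
    attractor <- if (object_present) object_deg else image_center_deg
    x_scale <- if (contrast == "low") opts$low_contrast_x_scale else 1
    t_used <- lat + first_fix
    while (t_used < opts$trial_dur_ms) {
      last <- c(fx$x_deg[nrow(fx)], fx$y_deg[nrow(fx)])
      if (stats::runif(1) < opts$p_micro) {
        # refixation: small step in a random direction
        amp <- stats::runif(1, opts$micro_amp[1], opts$micro_amp[2])
        ang <- stats::runif(1, 0, 2 * pi)
        nxt <- last + amp * c(cos(ang), sin(ang))
      } else if (stats::runif(1) < opts$attractor_weight) {
        nxt <- attractor + stats::rnorm(2, 0, opts$attractor_sd) * c(x_scale, 1)
      } else {
        # exploration step into the (central part of the) image
        nxt <- image_center_deg +
          stats::runif(2, -0.5, 0.5) * opts$uniform_span * opts$image_deg * c(x_scale, 1)
      }
      dur <- stats::rgamma(1, opts$fix_shape, opts$fix_shape / opts$fix_mean)
      fx <- rbind(fx, data.frame(x_deg = nxt[1], y_deg = nxt[2], duration_ms = dur))
      t_used <- t_used + dur + 2.2 * sqrt(sum((nxt - last)^2)) + 21
    }
    list(fixations = fx, anticipatory = anticipatory, latency_ms = lat)
  })
}

#' Generate a full synthetic experiment
#'
#' `"exp1"`: for each participant, three condition blocks of 200 trials
#' each (the full image x direction x displacement x mirroring crossing).
#' Per condition the attractor and bias-window amplitude differ: in
#' `look_center` the salient object (separation 2.2 deg) pulls strongly; in
#' `look_object` the image center (2.2 deg) pulls more weakly; in
#' `look_cue` the object (about 2 deg from the cue) dominates and latencies
#' are bimodal (saccadic inhibition after the image replaces the cue).
#'
#' `"exp2"`: per participant, the 512-trial exploration design (or a
#' scaled-down `n_trials`); each trial yields a fixation schedule, an event
#' table with every saccade, and (optionally, `traces = TRUE`) raw 1 kHz
#' sample streams.
#'
#' @param preset `"exp1"` or `"exp2"`.
#' @param n_participants number of participants (18 / 24 in the source
#'   designs).
#' @param seed master seed; everything derives deterministically from it.
#' @param n_trials optional trial count override per participant.
#' @param traces exp2 only: also generate raw sample streams.
#' @param mode exp1 only: `"bias"` (default) or `"capture"`.
#' @return list with `trials` and `events` data.frames covering all
#'   participants (exp2 additionally `samples` when `traces = TRUE`, plus
#'   per-trial `anticipatory` flags in the trial table).
#' @export
generate_experiment <- function(preset = c("exp1", "exp2"),
                                n_participants = NULL, seed = 1L,
                                n_trials = NULL, traces = FALSE,
                                mode = "bias") {
  preset <- match.arg(preset)
  if (preset == "exp1") {
    n_participants <- n_participants %||% 18L
    conds <- list(
      look_center = list(sep = 2.2, A = 0.75, inhib = FALSE),
      look_object = list(sep = 2.2, A = 0.35, inhib = FALSE),
      look_cue    = list(sep = 2.0, A = 0.6,  inhib = TRUE)
    )
    all_tr <- list(); all_ev <- list()
    for (p in seq_len(n_participants)) {
      pid <- sprintf("p%02d", p)
      for (cond in names(conds)) {
        cc <- conds[[cond]]
        par <- generator_params(mode = mode,
                                n_trials = n_trials %||% 200L,
                                separation_deg = cc$sep,
                                profile = bias_profile(amplitude = cc$A),
                                inhibition = cc$inhib)
        g <- generate_endpoint_trials(par, seed = derive_seed(seed, paste0(pid, cond)),
                                      participant_id = pid, condition = cond)
        g$trials$trial_id <- paste0(cond, "_", g$trials$trial_id)
        g$events$trial_id <- paste0(cond, "_", g$events$trial_id)
        all_tr[[length(all_tr) + 1L]] <- g$trials
        all_ev[[length(all_ev) + 1L]] <- g$events
      }
    }
    tr <- do.call(rbind, all_tr); ev <- do.call(rbind, all_ev)
    rownames(tr) <- rownames(ev) <- NULL
    return(list(trials = tr, events = ev))
  }
  # exp2
  n_participants <- n_participants %||% 24L
  opts <- scanpath_defaults()
  all_tr <- list(); all_ev <- list(); all_sm <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%02d", p)
    des <- design_preset("exp2", shuffle_seed = derive_seed(seed, paste0(pid, "design")))
    if (!is.null(n_trials)) des <- des[seq_len(min(n_trials, nrow(des))), , drop = FALSE]
    for (i in seq_len(nrow(des))) {
      row <- des[i, ]
      shift <- if (row$shift == "right") 3.52 else -3.52
      img_c <- c(shift, 0)
      obj <- c(-shift, 0)    # object and image center straddle the screen center
      fix0 <- c(0, if (row$fixation == "top") 11 else -11)
      tid <- sprintf("%s_t%04d", pid, i)
      tseed <- derive_seed(seed, tid)
      sim <- generate_exploration_trial(row$object_present, row$contrast,
                                        img_c, obj, fix0, opts, seed = tseed)
      if (traces) {
        tr <- generate_gaze_trace(sim$fixations, seed = derive_seed(seed, paste0(tid, "n")),
                                  t0_ms = 0, trial_id = tid)
        ev <- tr$events
        all_sm[[length(all_sm) + 1L]] <- tr$samples
      } else {
        ev <- schedule_events(sim$fixations, t0_ms = 0, trial_id = tid)
      }
      all_tr[[length(all_tr) + 1L]] <- data.frame(
        trial_id = tid, participant_id = pid, condition = "explore",
        image = row$image, object_present = row$object_present,
        contrast = row$contrast, shift = row$shift, fixation = row$fixation,
        mirrored = row$mirrored, axis = "x",
        displacement_sign = if (row$shift == "right") -1 else 1,
        goal_x = img_c[1], goal_y = img_c[2],
        attractor_x = obj[1], attractor_y = obj[2],
        center_x = img_c[1], center_y = img_c[2],
        anticipatory = sim$anticipatory, latency_ms = sim$latency_ms,
        stringsAsFactors = FALSE)
      all_ev[[length(all_ev) + 1L]] <- ev
    }
  }
  out <- list(trials = do.call(rbind, all_tr), events = do.call(rbind, all_ev))
  rownames(out$trials) <- rownames(out$events) <- NULL
  if (traces) {
    out$samples <- do.call(rbind, all_sm)
    rownames(out$samples) <- NULL
  }
  out
}
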