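test_that("generators are pure functions of (params, seed)", {
  p <- generator_params()
  g1 <- generate_endpoint_trials(p, seed = 12)
  g2 <- generate_endpoint_trials(p, seed = 12)
  expect_identical(g1, g2)
  g3 <- generate_endpoint_trials(p, seed = 13)
  expect_false(identical(g1$events$onset_ms, g3$events$onset_ms))
  e1 <- generate_experiment("exp2", n_participants = 1, seed = 4, n_trials = 6)
  e2 <- generate_experiment("exp2", n_participants = 1, seed = 4, n_trials = 6)
  expect_identical(e1, e2)
})

test_that("zero bias amplitude leaves endpoints on the goal", {
  p <- generator_params(profile = bias_profile(amplitude = 0), n_trials = 600)
  g <- generate_endpoint_trials(p, seed = 5)
  rec <- recode_endpoints(g$events, g$trials)
  expect_lt(abs(mean(rec$endpoint_rel_deg)), 3 * 0.7 / sqrt(600))
})

test_that("a saturated wide bias window centers endpoints on the attractor", {
  p <- generator_params(profile = bias_profile(amplitude = 1, width_ms = 1e9),
                        n_trials = 400, separation_deg = 2)
  g <- generate_endpoint_trials(p, seed = 6)
  rec <- recode_endpoints(g$events, g$trials)
  expect_equal(mean(rec$endpoint_rel_deg), 2, tolerance = 0.15)
})

test_that("capture exceeds bias variance by w(1-w)d^2 at matched windows", {
  prof <- bias_profile(amplitude = 0.5, width_ms = 1e9)  # constant w = 0.5
  pb <- generator_params(mode = "bias", profile = prof, n_trials = 3000)
  pc <- generator_params(mode = "capture", profile = prof, n_trials = 3000)
  vb <- var(recode_endpoints(generate_endpoint_trials(pb, seed = 7)$events,
                             generate_endpoint_trials(pb, seed = 7)$trials)$endpoint_rel_deg)
  vc <- var(recode_endpoints(generate_endpoint_trials(pc, seed = 7)$events,
                             generate_endpoint_trials(pc, seed = 7)$trials)$endpoint_rel_deg)
  # law of total variance: extra variance = w(1-w) d^2 = 0.25 * 4 = 1
  expect_equal(vc - vb, 1, tolerance = 0.15)
  # identical mean time course
  mb <- mean(recode_endpoints(generate_endpoint_trials(pb, seed = 8)$events,
                              generate_endpoint_trials(pb, seed = 8)$trials)$endpoint_rel_deg)
  mc <- mean(recode_endpoints(generate_endpoint_trials(pc, seed = 8)$events,
                              generate_endpoint_trials(pc, seed = 8)$trials)$endpoint_rel_deg)
  expect_equal(mb, mc, tolerance = 0.1)
})

test_that("gaze traces follow the main sequence and carry ground truth", {
  fx <- data.frame(x_deg = c(0, 8), y_deg = c(0, 0), duration_ms = c(100, 100))
  tr <- generate_gaze_trace(fx, sample_noise_sd = 0, seed = 1)
  # 8 deg saccade: duration 2.2 * 8 + 21 = 38.6 -> rounded trace segment
  expect_equal(tr$events$offset_ms - tr$events$onset_ms, round(38.6))
  expect_equal(tr$events$amplitude_deg, 8)
  # single fixation: constant trace, no events
  tr0 <- generate_gaze_trace(data.frame(x_deg = 1, y_deg = 2, duration_ms = 500),
                             sample_noise_sd = 0, seed = 1)
  expect_null(tr0$events)
  expect_equal(unique(tr0$samples$x_deg), 1)
  # schedule-only event bookkeeping agrees with the full trace
  fx2 <- data.frame(x_deg = c(0, 5, -1), y_deg = c(0, 2, 0),
                    duration_ms = c(120, 250, 300))
  tr2 <- generate_gaze_trace(fx2, sample_noise_sd = 0, seed = 2)
  sch <- gazebias:::schedule_events(fx2, t0_ms = 0, trial_id = "t0001")
  expect_equal(sch$onset_ms, tr2$events$onset_ms)
  expect_equal(sch$offset_ms, tr2$events$offset_ms)
})

test_that("experiment presets have the right shape", {
  e1 <- generate_experiment("exp1", n_participants = 2, seed = 9, n_trials = 20)
  expect_equal(sort(unique(e1$trials$condition)),
               c("look_center", "look_cue", "look_object"))
  expect_equal(nrow(e1$trials), 2 * 3 * 20)
  expect_equal(nrow(e1$events), nrow(e1$trials))
  e2 <- generate_experiment("exp2", n_participants = 1, seed = 9, n_trials = 8,
                            traces = TRUE)
  expect_equal(nrow(e2$trials), 8)
  expect_true(all(e2$events$index_in_trial >= 1))
  expect_true(!is.null(e2$samples))
  # traces sampled at 1 kHz from image onset
  s1 <- e2$samples[e2$samples$trial_id == e2$trials$trial_id[1], ]
  expect_equal(diff(s1$t_ms[1:10]), rep(1, 9))
})
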