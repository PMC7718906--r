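make_profiles <- function(threshold = 0.2, seed = 201, A = 10) {
  mvc <- emg_trace(A * generate_vemg(2, 1000, rms = 1, seed = seed)$value, 1000)
  rest <- emg_trace(0.01 * A * generate_vemg(2, 1000, rms = 1,
                                             seed = seed + 1)$value, 1000)
  p <- calibrate(mvc, rest, threshold = threshold)
  list(edc = p, fds = p)
}

test_that("power envelope is a causal moving average of squared samples", {
  fs <- 1000
  # constant c: c^2 after warm-up, growing-window before
  e <- power_envelope(rep(2, 500), window_ms = 100, fs = fs)
  expect_equal(e$value[100:500], rep(4, 401))
  expect_equal(e$value[1], 4) # single-sample window start
  expect_equal(power_envelope(numeric(100), 50, fs = fs)$value, numeric(100))

  # sine of amplitude A with a long window: ~ A^2 / 2
  s <- 3 * sin(2 * pi * 50 * (1:4000) / fs)
  e2 <- power_envelope(s, window_ms = 1000, fs = fs)
  expect_equal(e2$value[4000], 9 / 2, tolerance = 0.01)

  # causality: the envelope at n ignores later samples
  x <- c(numeric(300), rep(5, 200))
  e3 <- power_envelope(x, 100, fs = fs)
  expect_equal(e3$value[1:300], numeric(300))
})

test_that("calibration separates MVC from baseline", {
  mvc <- emg_trace(generate_vemg(2, 1000, rms = 2, seed = 211)$value, 1000)
  rest0 <- emg_trace(numeric(2000), 1000)
  p <- calibrate(mvc, rest0, threshold = 0.2)
  expect_equal(p$baseline_power, 0)
  expect_gt(p$mvc_power, 0)

  # MVC identical to rest is inseparable
  expect_error(calibrate(mvc, mvc), class = "vemg_error_data")

  # power scales with amplitude^2: 10x RMS -> ~100x power
  quiet <- generate_vemg(4, 1000, rms = 1, seed = 212)
  loud <- emg_trace(10 * quiet$value, 1000)
  p2 <- calibrate(loud, quiet, threshold = 0.2)
  expect_equal(p2$mvc_power / max(power_envelope(quiet, 200)$value), 100,
               tolerance = 1e-9)

  expect_error(calibrate(mvc, rest0, threshold = 1.2),
               class = "vemg_error_parameter")
})

test_that("reference normalization maps baseline to 0 and MVC to 1", {
  prof <- structure(list(mvc_power = 10, baseline_power = 2, threshold = 0.2,
                         window_ms = 200), class = "calibration_profile")
  expect_equal(to_reference(2, prof), 0)
  expect_equal(to_reference(10, prof), 1)
  expect_equal(to_reference(6, prof), 0.5)
  expect_equal(to_reference(0, prof), 0)   # clamped below
  expect_equal(to_reference(99, prof), 1)  # clamped above
})

test_that("intent detection honours thresholds, hysteresis and mutual exclusion", {
  cfg <- control_config()
  thr <- c(edc = 0.2, fds = 0.2)

  # both below threshold: rest
  d <- detect_intent(0.1, 0.15, cfg, thr)
  expect_equal(d$intent, "rest")
  expect_false(any(d$active))

  # both above with mutual exclusion: larger reference wins
  d2 <- detect_intent(0.6, 0.4, cfg, thr)
  expect_equal(d2$intent, "extension")
  expect_true(d2$active[["edc"]] && !d2$active[["fds"]])

  # mutual exclusion off: both stay active
  cfg_off <- control_config(mutual_exclusion = FALSE)
  d3 <- detect_intent(0.6, 0.4, cfg_off, thr)
  expect_true(all(d3$active))

  # flexion side
  d4 <- detect_intent(0.1, 0.5, cfg, thr)
  expect_equal(d4$intent, "flexion")

  # double-threshold hysteresis: stays on between off- and on-thresholds
  cfg_h <- control_config(threshold_mode = "double", off_fraction = 0.5)
  held <- detect_intent(0.15, 0, cfg_h, thr, was_active = c(edc = TRUE, fds = FALSE))
  expect_true(held$active[["edc"]])
  fresh <- detect_intent(0.15, 0, cfg_h, thr, was_active = c(edc = FALSE, fds = FALSE))
  expect_false(fresh$active[["edc"]])
})

test_that("reference-to-pulsewidth map is proportional above threshold", {
  expect_equal(reference_to_pulsewidth(0.1, 0.2, 50, 300), 0)
  expect_equal(reference_to_pulsewidth(1, 0.2, 50, 300), 300)
  expect_equal(reference_to_pulsewidth(0.2, 0.2, 50, 300), 50)
  expect_equal(reference_to_pulsewidth(0.6, 0.2, 50, 300), 175)
  # monotone non-decreasing
  pw <- reference_to_pulsewidth(seq(0, 1, 0.01), 0.2, 50, 300)
  expect_true(all(diff(pw) >= 0))
  expect_error(reference_to_pulsewidth(0.5, 0.2, 300, 50),
               class = "vemg_error_config")
})

test_that("pulsewidth smoothing follows the slew recurrence exactly", {
  # sign(0) = 0 holds the pulsewidth
  expect_equal(smooth_pulsewidth(10, 10, 0.1), 10)

  # one tick from rest toward 100: exactly eta
  expect_equal(smooth_pulsewidth(100, 0, 0.1), 0.1)

  # iterating 1000 ticks at eta = 0.1 covers exactly 100 (1 s at 1000 Hz)
  p <- 0
  for (i in 1:1000) p <- smooth_pulsewidth(100, p, 0.1)
  expect_equal(p, 100, tolerance = 1e-9)

  # slew invariant: |p_a[n] - p_a[n-1]| <= eta for arbitrary targets
  set.seed(221)
  targets <- runif(500, 0, 300)
  pa <- 0
  for (t in targets) {
    pa_next <- smooth_pulsewidth(t, pa, 0.1)
    expect_lte(abs(pa_next - pa), 0.1 + 1e-12)
    pa <- pa_next
  }

  expect_error(smooth_pulsewidth(1, 0, 0), class = "vemg_error_parameter")
})

test_that("the per-tick controller decays, ramps and saturates correctly", {
  cfg <- control_config(eta = 0.1, pw_min = 50, pw_max = 300,
                        power_window_ms = 50)
  profiles <- make_profiles(threshold = 0.2)
  st <- new_control_state(cfg, profiles)

  # zero input forever: both applied pulsewidths stay at 0
  for (i in 1:50) {
    r <- step_controller(st, 0, 0)
    st <- r$state
  }
  expect_equal(unname(st$p_a), c(0, 0))
  expect_equal(r$feedback, 0)
  expect_equal(r$intent, "rest")
  expect_equal(r$commands$pulsewidth_us, c(0, 0))
  expect_equal(r$commands$frequency_hz, c(25, 25))

  # step EDC activation: p_a ramps at exactly eta per tick
  A <- sqrt(profiles$edc$mvc_power) # sample amplitude giving reference ~1
  prev <- 0
  deltas <- numeric(0)
  for (i in 1:400) {
    r <- step_controller(st, 2 * A, 0)
    st <- r$state
    deltas <- c(deltas, st$p_a[["edc"]] - prev)
    prev <- st$p_a[["edc"]]
  }
  expect_true(all(abs(deltas) <= cfg$eta + 1e-12))
  expect_true(all(abs(deltas[100:400] - cfg$eta) < 1e-9)) # sustained ramp
  expect_equal(r$intent, "extension")

  # sustained drive saturates at pw_max and never exceeds it
  for (i in 1:4000) st <- step_controller(st, 2 * A, 0)$state
  expect_lte(st$p_a[["edc"]], cfg$pw_max)

  expect_error(new_control_state(cfg, list(edc = 1, fds = 2)),
               class = "vemg_error_state")
})

test_that("run_controller replays step_controller tick-for-tick", {
  cfg <- control_config(eta = 0.5, pw_min = 20, pw_max = 100,
                        power_window_ms = 20)
  profiles <- make_profiles(threshold = 0.2, seed = 231)
  n <- 400
  edc <- generate_vemg(n / 1000, 1000, rms = 2, seed = 232)
  fds <- generate_vemg(n / 1000, 1000, rms = 0.5, seed = 233)

  log <- run_controller(edc, fds, cfg, profiles)
  expect_equal(nrow(log), n)

  st <- new_control_state(cfg, profiles)
  pa_e <- numeric(n); fb <- numeric(n); ref_e <- numeric(n)
  for (i in seq_len(n)) {
    r <- step_controller(st, edc$value[i], fds$value[i])
    st <- r$state
    pa_e[i] <- st$p_a[["edc"]]; fb[i] <- r$feedback
    ref_e[i] <- r$reference[["edc"]]
  }
  expect_equal(log$pa_edc, pa_e, tolerance = 1e-12)
  expect_equal(log$feedback, fb, tolerance = 1e-12)
  expect_equal(log$ref_edc, ref_e, tolerance = 1e-12)

  # slew invariant over the whole log
  expect_true(all(abs(diff(log$pa_edc)) <= cfg$eta + 1e-12))
  expect_true(all(abs(diff(log$pa_fds)) <= cfg$eta + 1e-12))

  # proportional steady state: constant supra-threshold reference converges
  # to within eta of the linear map
  const <- emg_trace(rep(sqrt(0.5 * profiles$edc$mvc_power), 3000), 1000)
  silent <- emg_trace(numeric(3000), 1000)
  log2 <- run_controller(const, silent, cfg, profiles)
  r_ss <- log2$ref_edc[3000]
  target <- reference_to_pulsewidth(r_ss, 0.2, cfg$pw_min, cfg$pw_max)
  expect_lt(abs(log2$pa_edc[3000] - target), cfg$eta + 1e-9)
})

test_that("feedback is the pulsewidth difference normalized by pw_max", {
  expect_equal(compute_feedback(120, 120, 300), 0)
  expect_equal(compute_feedback(300, 0, 300), 1)
  expect_equal(compute_feedback(0, 150, 300), -0.5)
  expect_error(compute_feedback(1, 1, 0), class = "vemg_error_parameter")
})

test_that("target shape is trapezoidal with exact flat-region masks", {
  fs <- 100
  sh <- generate_target_shape(20, flat_level = 0.8, flat_duration_s = 4,
                              fs_display = fs)
  expect_equal(nrow(sh), 2000L)
  expect_true(all(abs(sh$target) <= 0.8 + 1e-12))
  expect_equal(sum(sh$ext_flat), 4 * fs)
  expect_equal(sum(sh$flex_flat), 4 * fs)
  expect_true(all(sh$target[sh$ext_flat] == 0.8))
  expect_true(all(sh$target[sh$flex_flat] == -0.8))

  # zero plateau duration: triangular, empty masks
  tri <- generate_target_shape(10, 0.5, 0, fs_display = fs)
  expect_false(any(tri$ext_flat) || any(tri$flex_flat))

  # full-scale plateau
  full <- generate_target_shape(20, 1, 2, fs_display = fs)
  expect_equal(range(full$target), c(-1, 1))
})

test_that("tracing scores report correlations and flat-region RMSE", {
  sh <- generate_target_shape(20, 0.8, 4, fs_display = 100)

  # feedback equal to the target: perfect correlation, zero RMSE
  s1 <- score_tracing(sh$target, sh, emg_power_diff = sh$target)
  expect_equal(s1$corr_feedback_target, 1)
  expect_equal(s1$corr_feedback_emg, 1)
  expect_equal(s1$rmse_extension_flat, 0)
  expect_equal(s1$rmse_flexion_flat, 0)

  # inverted feedback: correlation -1
  expect_equal(score_tracing(-sh$target, sh)$corr_feedback_target, -1)

  # constant offset on the flats: RMSE = |d|
  s3 <- score_tracing(sh$target + 0.07, sh)
  expect_equal(s3$rmse_extension_flat, 0.07, tolerance = 1e-12)
  expect_equal(s3$rmse_flexion_flat, 0.07, tolerance = 1e-12)

  # constant feedback: correlation undefined, flagged as NA with a warning
  expect_warning(s4 <- score_tracing(rep(0.1, nrow(sh)), sh))
  expect_true(is.na(s4$corr_feedback_target))
})
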