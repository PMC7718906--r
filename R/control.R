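#' Controller configuration
#'
#' Parameters of the proportional EMG-to-pulsewidth control chain. The
#' controller ticks at the EMG sampling rate (1 ms at 1000 Hz); the
#' applied pulsewidth may change by at most `eta` microseconds per tick
#' (0.1 at the operating point, i.e. 100 microseconds per second),
#' giving a smooth rise and fall that reduces discomfort.
#'
#' @param fs controller tick rate in Hz (equals the EMG sampling rate).
#' @param f_stim stimulation frequency in Hz.
#' @param eta slew step in microseconds per tick.
#' @param pw_min,pw_max pulsewidth range in microseconds mapped onto the
#'   supra-threshold reference range.
#' @param current_mA stimulation current; clinically 10-28 mA.
#' @param power_window_ms smoothing window of the power envelope.
#' @param threshold_mode `"single"` (one activation threshold) or
#'   `"double"` (hysteresis: the off threshold is
#'   `off_fraction * threshold`).
#' @param off_fraction hysteresis release fraction in double mode.
#' @param mutual_exclusion allow only the channel with the larger
#'   reference to stay active.
#' @return A list of class `control_config`.
#' @export
control_config <- function(fs = 1000, f_stim = 25, eta = 0.1,
                           pw_min = 50, pw_max = 300, current_mA = 20,
                           power_window_ms = 200,
                           threshold_mode = c("single", "double"),
                           off_fraction = 0.5,
                           mutual_exclusion = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  if (eta <= 0) stop_parameter("`eta` must be positive.")
  if (pw_max < pw_min || pw_min < 0)
    stop_config("Pulsewidths must satisfy 0 <= pw_min <= pw_max.")
  if (current_mA < 0 || current_mA > 100)
    stop_config("`current_mA` outside the safe range.")
  if (power_window_ms < 1) stop_parameter("`power_window_ms` must be >= 1 ms.")
  structure(list(fs = fs, f_stim = f_stim, eta = eta,
                 pw_min = pw_min, pw_max = pw_max, current_mA = current_mA,
                 power_window_ms = power_window_ms,
                 threshold_mode = threshold_mode,
                 off_fraction = off_fraction,
                 mutual_exclusion = isTRUE(mutual_exclusion)),
            class = "control_config")
}

#' Smoothed EMG power envelope
#'
#' Causal moving average of the squared samples over `window_ms`. Early
#' samples use the growing partial window, so the output has the input's
#' length and no lookahead.
#'
#' @param trace an [emg_trace()] or numeric vector.
#' @param window_ms window length in milliseconds.
#' @param fs sampling rate, taken from the trace when available.
#' @return An [emg_trace()] of smoothed power (amplitude-squared units).
#' @export
power_envelope <- function(trace, window_ms = 200, fs = NULL) {
  fs <- fs %||% if (is.data.frame(trace)) trace_fs(trace) else
    stop_parameter("`fs` is required for vector input.")
  x <- trace_values(trace)
  w <- max(1L, round(window_ms * fs / 1000))
  cs <- cumsum(x^2)
  n <- length(x)
  env <- (cs - c(numeric(min(w, n)), cs[seq_len(max(0, n - w))])) /
    pmin(seq_len(n), w)
  emg_trace(env, fs = fs, label = "power")
}

#' Calibrate a channel from MVC and rest recordings
#'
#' The controller normalizes live EMG power against a maximum voluntary
#' contraction (MVC): the MVC power is the peak of the smoothed envelope
#' during the contraction, the baseline is the median envelope at rest.
#'
#' @param mvc_trace extracted EMG recorded during maximum voluntary
#'   contraction (FES off).
#' @param rest_trace extracted EMG at rest.
#' @param window_ms envelope smoothing window in milliseconds.
#' @param threshold activation threshold as a fraction of the normalized
#'   (baseline-to-MVC) range, in (0, 1).
#' @return A list of class `calibration_profile` with `mvc_power`,
#'   `baseline_power`, `threshold`, `window_ms`.
#' @export
calibrate <- function(mvc_trace, rest_trace, window_ms = 200, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1)
    stop_parameter("`threshold` must be in (0, 1).")
  mvc_env <- power_envelope(mvc_trace, window_ms)$value
  mvc <- max(mvc_env)
  base <- stats::median(power_envelope(rest_trace, window_ms)$value)
  # a usable MVC must be separable from rest in sustained level, not just
  # in a single envelope peak
  if (mvc <= base || stats::median(mvc_env) <= base)
    stop_data("Calibration failed: MVC power does not exceed the resting baseline.")
  structure(list(mvc_power = mvc, baseline_power = base,
                 threshold = threshold, window_ms = window_ms),
            class = "calibration_profile")
}

#' Normalized effort reference
#'
#' Maps smoothed power onto `[0, 1]` relative to the calibration:
#' `(power - baseline) / (mvc - baseline)`, clamped. 0 is rest, 1 is
#' the calibrated maximum voluntary contraction.
#'
#' @param power smoothed power value(s).
#' @param profile a [calibrate()] result.
#' @return Reference value(s) in `[0, 1]`.
#' @export
to_reference <- function(power, profile) {
  stopifnot(inherits(profile, "calibration_profile"))
  r <- (power - profile$baseline_power) /
    (profile$mvc_power - profile$baseline_power)
  pmin(pmax(r, 0), 1)
}

#' Detect movement intent from the two references
#'
#' A channel is active when its reference reaches its threshold (single
#' mode) or per hysteresis (double mode: turns on at the threshold,
#' stays on until it falls below `off_fraction * threshold`). With
#' mutual exclusion, only the channel with the larger reference remains
#' active, preventing co-stimulation of the antagonists. Intent is
#' extension when the extensor (EDC) drives, flexion when the flexor
#' (FDS) does, rest otherwise.
#'
#' @param ref_edc,ref_fds references in `[0, 1]`.
#' @param config a [control_config()].
#' @param thresholds named numeric, activation thresholds per channel.
#' @param was_active named logical, previous activation (for hysteresis).
#' @return A list: `intent` (`"extension"`, `"flexion"`, `"rest"`) and
#'   `active` (named logical for `edc`, `fds`).
#' @export
detect_intent <- function(ref_edc, ref_fds, config = control_config(),
                          thresholds = c(edc = 0.2, fds = 0.2),
                          was_active = c(edc = FALSE, fds = FALSE)) {
  on_at <- thresholds
  off_at <- if (config$threshold_mode == "double")
    thresholds * config$off_fraction else thresholds
  refs <- c(edc = ref_edc, fds = ref_fds)
  active <- ifelse(was_active, refs >= off_at, refs >= on_at)
  names(active) <- c("edc", "fds")
  if (config$mutual_exclusion && all(active)) {
    keep <- if (refs["edc"] >= refs["fds"]) "edc" else "fds"
    active[setdiff(names(active), keep)] <- FALSE
  }
  intent <- if (active["edc"] && (!active["fds"] || refs["edc"] >= refs["fds"]))
    "extension"
  else if (active["fds"]) "flexion"
  else "rest"
  list(intent = intent, active = active)
}

#' Map a reference to the computed pulsewidth
#'
#' Proportional regime: 0 below the threshold; at and above it, the
#' reference interval `[threshold, 1]` maps linearly onto
#' `[pw_min, pw_max]`, so stimulation intensity is proportional to the
#' voluntary effort above threshold.
#'
#' @param reference value(s) in `[0, 1]`.
#' @param threshold activation threshold in (0, 1).
#' @param pw_min,pw_max pulsewidth range in microseconds.
#' @return Computed pulsewidth(s) `p_c` in microseconds.
#' @export
reference_to_pulsewidth <- function(reference, threshold, pw_min, pw_max) {
  if (pw_max < pw_min) stop_config("`pw_max` must be at least `pw_min`.")
  span <- pmax(1 - threshold, .Machine$double.eps)
  pc <- pw_min + (reference - threshold) / span * (pw_max - pw_min)
  ifelse(reference < threshold, 0, pmin(pmax(pc, pw_min), pw_max))
}

#' Slew-rate-limited pulsewidth smoothing
#'
#' The applied pulsewidth follows
#' `p_a[n] = p_a[n-1] + sign(p_c[n] - p_a[n-1]) * eta`,
#' with `sign(0) = 0` so the pulsewidth holds once converged. Run at the
#' EMG rate (1000 Hz) with `eta = 0.1`, the applied pulsewidth ramps at
#' 100 microseconds per second toward the computed target.
#'
#' @param p_c computed pulsewidth at this tick, microseconds.
#' @param p_a_prev applied pulsewidth at the previous tick.
#' @param eta step size in microseconds per tick.
#' @return The applied pulsewidth `p_a`.
#' @export
smooth_pulsewidth <- function(p_c, p_a_prev, eta = 0.1) {
  if (eta <= 0) stop_parameter("`eta` must be positive.")
  p_a_prev + sign(p_c - p_a_prev) * eta
}

#' Initialize controller state
#'
#' @param config a [control_config()].
#' @param profiles named list with `calibration_profile`s for `edc` and
#'   `fds`.
#' @return A list of class `control_state`.
#' @export
new_control_state <- function(config = control_config(), profiles) {
  if (!all(c("edc", "fds") %in% names(profiles)) ||
      !all(vapply(profiles, inherits, TRUE, "calibration_profile")))
    stop_state("Controller requires calibration profiles for both `edc` and `fds`.")
  w <- max(1L, round(config$power_window_ms * config$fs / 1000))
  structure(
    list(config = config, profiles = profiles, window = w,
         buf = list(edc = numeric(w), fds = numeric(w)),
         buf_pos = 0L, buf_n = 0L,
         sumsq = c(edc = 0, fds = 0),
         p_a = c(edc = 0, fds = 0),
         active = c(edc = FALSE, fds = FALSE),
         tick = 0L),
    class = "control_state"
  )
}

#' Advance the controller by one tick
#'
#' One 1 ms control step: update the power envelopes with the newest
#' extracted-EMG samples, normalize to references, detect intent, map
#' the active channels' references to computed pulsewidths, slew-limit
#' them into applied pulsewidths (inactive channels decay to zero
#' through the same recurrence), and emit the stimulator commands and
#' the visual-feedback value `(EDC_pw - FDS_pw) / pw_max`.
#'
#' @param state a [new_control_state()].
#' @param edc_sample,fds_sample newest extracted-EMG samples.
#' @return A list: `state` (advanced), `commands` (tibble, one row per
#'   channel: `channel`, `pulsewidth_us`, `current_mA`, `frequency_hz`,
#'   `tick`), `feedback` (scalar in `[-1, 1]`), `intent`, `reference`
#'   (named numeric).
#' @export
step_controller <- function(state, edc_sample, fds_sample) {
  stopifnot(inherits(state, "control_state"))
  cfg <- state$config
  w <- state$window
  pos <- state$buf_pos %% w + 1L
  new <- c(edc = edc_sample^2, fds = fds_sample^2)
  old <- c(edc = state$buf$edc[pos], fds = state$buf$fds[pos])
  state$sumsq <- state$sumsq + new - old
  state$buf$edc[pos] <- new["edc"]; state$buf$fds[pos] <- new["fds"]
  state$buf_pos <- pos
  state$buf_n <- min(state$buf_n + 1L, w)
  power <- state$sumsq / state$buf_n

  ref <- c(edc = to_reference(power[["edc"]], state$profiles$edc),
           fds = to_reference(power[["fds"]], state$profiles$fds))
  det <- detect_intent(ref[["edc"]], ref[["fds"]], cfg,
                       thresholds = c(edc = state$profiles$edc$threshold,
                                      fds = state$profiles$fds$threshold),
                       was_active = state$active)
  state$active <- det$active

  p_c <- c(edc = 0, fds = 0)
  for (ch in c("edc", "fds")) if (det$active[[ch]])
    p_c[[ch]] <- reference_to_pulsewidth(ref[[ch]], state$profiles[[ch]]$threshold,
                                         cfg$pw_min, cfg$pw_max)
  state$p_a <- pmin(pmax(smooth_pulsewidth(p_c, state$p_a, cfg$eta), 0), cfg$pw_max)
  state$tick <- state$tick + 1L

  commands <- tibble(channel = c("edc", "fds"),
                     pulsewidth_us = unname(state$p_a),
                     current_mA = cfg$current_mA,
                     frequency_hz = cfg$f_stim,
                     tick = state$tick)
  list(state = state,
       commands = commands,
       feedback = compute_feedback(state$p_a[["edc"]], state$p_a[["fds"]],
                                   cfg$pw_max),
       intent = det$intent, reference = ref)
}

#' Visual feedback value
#'
#' The on-screen feedback shown to the user is the normalized difference
#' of the applied pulsewidths, `(EDC_pw - FDS_pw) / pw_max`, in
#' `[-1, 1]`: positive when extension drive dominates, negative for
#' flexion.
#'
#' @param p_a_edc,p_a_fds applied pulsewidths in microseconds.
#' @param pw_max maximum pulsewidth.
#' @return Feedback value in `[-1, 1]`.
#' @export
compute_feedback <- function(p_a_edc, p_a_fds, pw_max) {
  if (pw_max <= 0) stop_parameter("`pw_max` must be positive.")
  (p_a_edc - p_a_fds) / pw_max
}

#' Run the controller over whole traces
#'
#' Offline replay of the per-tick controller over two extracted-EMG
#' channels; equivalent to calling [step_controller()] once per sample.
#'
#' @param edc_trace,fds_trace extracted-EMG [emg_trace()]s of equal
#'   length.
#' @param config a [control_config()].
#' @param profiles named list of calibration profiles (`edc`, `fds`).
#' @return A tibble with one row per tick: `tick`, `time`, `ref_edc`,
#'   `ref_fds`, `intent`, `pc_edc`, `pc_fds`, `pa_edc`, `pa_fds`,
#'   `feedback`.
#' @export
run_controller <- function(edc_trace, fds_trace, config = control_config(),
                           profiles) {
  edc <- trace_values(edc_trace); fds <- trace_values(fds_trace)
  check_equal_length(edc, fds)
  n <- length(edc)
  fs <- config$fs

  # vectorized envelope -> reference -> intent -> computed pulsewidth
  env_e <- power_envelope(edc, config$power_window_ms, fs = fs)$value
  env_f <- power_envelope(fds, config$power_window_ms, fs = fs)$value
  ref_e <- to_reference(env_e, profiles$edc)
  ref_f <- to_reference(env_f, profiles$fds)

  thr <- c(edc = profiles$edc$threshold, fds = profiles$fds$threshold)
  active <- c(edc = FALSE, fds = FALSE)
  intent <- character(n)
  pc_e <- numeric(n); pc_f <- numeric(n)
  for (i in seq_len(n)) {
    det <- detect_intent(ref_e[i], ref_f[i], config, thr, active)
    active <- det$active
    intent[i] <- det$intent
    if (active[["edc"]])
      pc_e[i] <- reference_to_pulsewidth(ref_e[i], thr[["edc"]],
                                         config$pw_min, config$pw_max)
    if (active[["fds"]])
      pc_f[i] <- reference_to_pulsewidth(ref_f[i], thr[["fds"]],
                                         config$pw_min, config$pw_max)
  }
  pa_e <- slew_track(pc_e, config$eta, config$pw_max)
  pa_f <- slew_track(pc_f, config$eta, config$pw_max)

  tibble(tick = seq_len(n), time = (seq_len(n) - 1) / fs,
         ref_edc = ref_e, ref_fds = ref_f, intent = intent,
         pc_edc = pc_e, pc_fds = pc_f, pa_edc = pa_e, pa_fds = pa_f,
         feedback = (pa_e - pa_f) / config$pw_max)
}

# iterate p_a[n] = p_a[n-1] + sign(p_c[n] - p_a[n-1]) * eta from 0
slew_track <- function(p_c, eta, pw_max) {
  out <- numeric(length(p_c))
  prev <- 0
  for (i in seq_along(p_c)) {
    prev <- min(max(prev + sign(p_c[i] - prev) * eta, 0), pw_max)
    out[i] <- prev
  }
  out
}

#' Trapezoidal tracing target
#'
#' The on-screen profile users trace during the tracing task: rest, ramp
#' up to an extension plateau, ramp down through rest to a flexion
#' plateau, and return. Flat-region masks mark the two plateaus for RMSE
#' scoring.
#'
#' @param duration_s total duration in seconds.
#' @param flat_level plateau level in (0, 1].
#' @param flat_duration_s plateau duration in seconds.
#' @param fs_display sample rate of the displayed profile in Hz.
#' @return A tibble of class `target_shape` with columns `time`,
#'   `target`, `ext_flat`, `flex_flat`.
#' @export
generate_target_shape <- function(duration_s = 30, flat_level = 0.8,
                                  flat_duration_s = 5, fs_display = 1000) {
  if (duration_s <= 0 || flat_duration_s < 0 || fs_display <= 0)
    stop_parameter("Durations and rate must be positive.")
  if (flat_level <= 0 || flat_level > 1)
    stop_parameter("`flat_level` must be in (0, 1].")
  n <- round(duration_s * fs_display)
  n_flat <- round(flat_duration_s * fs_display)
  # segments: rest | ramp+ | ext flat | ramp down (2x) | flex flat | ramp- | rest
  n_ramp <- max(1L, (n - 2L * n_flat) %/% 6L)
  n_rest <- n - 2L * n_flat - 4L * n_ramp
  n_rest1 <- n_rest %/% 2L
  seg <- c(rep(0, n_rest1),
           seq(0, flat_level, length.out = n_ramp + 1)[-1],
           rep(flat_level, n_flat),
           seq(flat_level, -flat_level, length.out = 2L * n_ramp + 1)[-1],
           rep(-flat_level, n_flat),
           seq(-flat_level, 0, length.out = n_ramp + 1)[-1])
  target <- c(seg, rep(0, n - length(seg)))
  flat <- rep(FALSE, n)
  ext_flat <- flat; flex_flat <- flat
  if (n_flat > 0) {
    i0 <- n_rest1 + n_ramp
    ext_flat[(i0 + 1):(i0 + n_flat)] <- TRUE
    j0 <- i0 + n_flat + 2L * n_ramp
    flex_flat[(j0 + 1):(j0 + n_flat)] <- TRUE
  }
  new_tibble(list(time = (seq_len(n) - 1) / fs_display, target = target,
                  ext_flat = ext_flat, flex_flat = flex_flat),
             fs_display = fs_display, class = "target_shape")
}

#' Score a tracing-task run
#'
#' Pearson correlations of the feedback with the extracted-EMG power
#' difference and with the target over the full trace, plus the RMSE of
#' the feedback against the target restricted to each plateau.
#'
#' @param feedback per-tick feedback values in `[-1, 1]`.
#' @param target a [generate_target_shape()] tibble of the same length.
#' @param emg_power_diff per-tick difference of the two channels'
#'   smoothed EMG power (optional; `NULL` skips that correlation).
#' @return A one-row tibble: `corr_feedback_emg`, `corr_feedback_target`,
#'   `rmse_extension_flat`, `rmse_flexion_flat`. Correlations with a
#'   constant input are undefined and returned as `NA` with a warning.
#' @export
score_tracing <- function(feedback, target, emg_power_diff = NULL) {
  check_equal_length(feedback, target$target)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warn("Correlation undefined for a constant sequence; returning NA.")
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  rmse <- function(mask) if (any(mask))
    sqrt(mean((feedback[mask] - target$target[mask])^2)) else NA_real_
  tibble(
    corr_feedback_emg = if (is.null(emg_power_diff)) NA_real_ else
      safe_cor(feedback, emg_power_diff),
    corr_feedback_target = safe_cor(feedback, target$target),
    rmse_extension_flat = rmse(target$ext_flat),
    rmse_flexion_flat = rmse(target$flex_flat)
  )
}

#' Plot a controller run against its target
#'
#' @param log tibble from [run_controller()].
#' @param target optional [generate_target_shape()] of the same length.
#' @return A ggplot object.
#' @export
plot_controller_run <- function(log, target = NULL) {
  df <- tibble(time = log$time, value = log$feedback, series = "feedback")
  if (!is.null(target))
    df <- dplyr::bind_rows(df, tibble(time = target$time,
                                      value = target$target,
                                      series = "target"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "normalized feedback", colour = NULL)
}
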