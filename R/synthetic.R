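#' Artifact model parameters
#'
#' Parameters of the simulated contamination added to synthetic voluntary
#' EMG: a one-sample stimulation pulse per stimulus, an m-wave transient
#' per stimulus with amplitude scale `alpha` and time constant `tau`
#' drawn uniformly per pulse, optional post-pulse amplifier saturation,
#' and an overall worst-case artifact magnitude expressed relative to
#' the voluntary-EMG RMS.
#'
#' Defaults reproduce the worst-case simulation conditions used to study
#' the filters: 25 Hz stimulation, `alpha` uniform on 200 +/- 20, `tau`
#' uniform on 20 +/- 5 samples, artifact peaks about 100 times the
#' voluntary-EMG RMS, and no clipping (post-stimulus saturation is an
#' optional amplifier effect, off by default).
#'
#' @param f_stim stimulation frequency in Hz.
#' @param alpha_mean,alpha_halfrange centre and half-range of the uniform
#'   m-wave amplitude scale.
#' @param tau_mean,tau_halfrange centre and half-range of the uniform
#'   m-wave time constant, in samples.
#' @param magnitude_ratio ratio of peak artifact amplitude to the clean
#'   voluntary-EMG RMS (100 = worst case).
#' @param clip_window number of samples saturated after each pulse (0-4).
#' @param clip_level saturation amplitude (ignored when `clip_window` is 0).
#' @return A list of class `artifact_params`.
#' @export
artifact_params <- function(f_stim = 25,
                            alpha_mean = 200, alpha_halfrange = 20,
                            tau_mean = 20, tau_halfrange = 5,
                            magnitude_ratio = 100,
                            clip_window = 0, clip_level = Inf) {
  if (f_stim <= 0) stop_parameter("`f_stim` must be positive.")
  if (alpha_halfrange < 0 || tau_halfrange < 0)
    stop_parameter("Half-ranges must be non-negative.")
  if (tau_mean - tau_halfrange <= 0)
    stop_parameter("`tau_mean - tau_halfrange` must be positive.")
  if (clip_window < 0 || clip_window > 4)
    stop_parameter("`clip_window` must be between 0 and 4 samples.")
  if (clip_level < 0) stop_parameter("`clip_level` must be non-negative.")
  structure(
    list(f_stim = f_stim,
         alpha_mean = alpha_mean, alpha_halfrange = alpha_halfrange,
         tau_mean = tau_mean, tau_halfrange = tau_halfrange,
         magnitude_ratio = magnitude_ratio,
         clip_window = as.integer(clip_window), clip_level = clip_level),
    class = "artifact_params"
  )
}

#' Generate band-limited Gaussian voluntary EMG
#'
#' Voluntary surface EMG during functional movement is modelled as
#' band-limited Gaussian noise. White Gaussian noise is passed through a
#' 4th-order zero-phase Butterworth band-pass and rescaled to the
#' requested RMS, giving a zero-mean trace whose spectral power is
#' concentrated in `band`.
#'
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz.
#' @param band two-element numeric, pass-band edges in Hz; the default
#'   20-450 Hz is the conventional surface-EMG bandwidth below the
#'   500 Hz Nyquist limit at 1000 Hz.
#' @param rms target root-mean-square amplitude.
#' @param seed integer seed; the draw is reproducible for a fixed seed
#'   and leaves the global RNG untouched. `NULL` uses the current RNG
#'   state.
#' @param label channel name.
#' @return An [emg_trace()].
#' @examples
#' v <- generate_vemg(1, fs = 1000, rms = 1, seed = 1)
#' trace_rms(v)
#' @export
generate_vemg <- function(duration_s, fs = 1000, band = c(20, 450),
                          rms = 1, seed = NULL, label = "vEMG") {
  if (duration_s <= 0) stop_parameter("`duration_s` must be positive.")
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop_parameter("`band` must satisfy 0 < low < high < fs/2.")
  if (rms < 0) stop_parameter("`rms` must be non-negative.")
  n <- round(duration_s * fs)
  if (rms == 0) return(emg_trace(numeric(n), fs = fs, label = label))
  white <- with_optional_seed(seed, stats::rnorm(n))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, white)
  x <- x - mean(x)
  x <- x * (rms / sqrt(mean(x^2)))
  emg_trace(x, fs = fs, label = label)
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Draw per-pulse m-wave parameters
#'
#' Each stimulation pulse evokes an m-wave whose amplitude scale `alpha`
#' and time constant `tau` vary from pulse to pulse; both are drawn
#' independently and uniformly within `mean +/- halfrange`.
#'
#' @param params an [artifact_params()].
#' @param n_pulses number of pulses.
#' @param seed integer seed, or `NULL` for the current RNG state.
#' @return A tibble with columns `pulse`, `alpha`, `tau`.
#' @export
sample_mwave_params <- function(params, n_pulses, seed = NULL) {
  stopifnot(inherits(params, "artifact_params"))
  if (n_pulses < 1) stop_parameter("`n_pulses` must be at least 1.")
  draws <- with_optional_seed(seed, {
    list(alpha = stats::runif(n_pulses,
                              params$alpha_mean - params$alpha_halfrange,
                              params$alpha_mean + params$alpha_halfrange),
         tau = stats::runif(n_pulses,
                            params$tau_mean - params$tau_halfrange,
                            params$tau_mean + params$tau_halfrange))
  })
  tibble(pulse = seq_len(n_pulses), alpha = draws$alpha, tau = draws$tau)
}

# m-wave kernel: gamma-like transient m(t) = alpha * t * exp(-t / tau),
# t in samples from pulse onset. Peaks at t = tau (about 20 ms at
# 1000 Hz, matching physiological m-wave latency) with value
# alpha * tau / e. Pluggable via the `kernel` argument of
# generate_mwave_train().
mwave_kernel <- function(t, alpha, tau) alpha * t * exp(-t / tau)

#' Superpose an m-wave train
#'
#' Builds the stimulus-evoked m-wave component: one kernel per pulse,
#' starting at its pulse index and truncated at the end of the trace.
#' Kernels from successive pulses overlap additively.
#'
#' @param fs sampling rate in Hz.
#' @param pulse_indices strictly increasing 1-based sample indices.
#' @param param_pairs data frame with one row per pulse and columns
#'   `alpha`, `tau` (see [sample_mwave_params()]).
#' @param length_out length of the output trace in samples.
#' @param kernel kernel function `f(t, alpha, tau)` evaluated at integer
#'   sample offsets `t >= 0` from pulse onset.
#' @return An [emg_trace()] containing only the m-wave train.
#' @export
generate_mwave_train <- function(fs, pulse_indices, param_pairs, length_out,
                                 kernel = mwave_kernel) {
  pulse_indices <- as.integer(pulse_indices)
  if (any(diff(pulse_indices) <= 0))
    stop_parameter("`pulse_indices` must be strictly increasing.")
  if (any(pulse_indices < 1L) || any(pulse_indices > length_out))
    stop_parameter("Pulse indices must lie within the trace.")
  if (nrow(param_pairs) != length(pulse_indices))
    stop_parameter("Need one (alpha, tau) pair per pulse.")
  out <- numeric(length_out)
  for (k in seq_along(pulse_indices)) {
    i0 <- pulse_indices[k]
    t <- 0:(length_out - i0)
    out[i0:length_out] <- out[i0:length_out] +
      kernel(t, param_pairs$alpha[k], param_pairs$tau[k])
  }
  emg_trace(out, fs = fs, label = "m-wave")
}

#' Add one-sample stimulation pulses
#'
#' The transient stimulation artifact is modelled as a single-sample
#' pulse of the given magnitude added at each pulse index; all other
#' samples are unchanged.
#'
#' @param trace an [emg_trace()].
#' @param pulse_indices 1-based sample indices.
#' @param magnitude pulse amplitude.
#' @return An [emg_trace()].
#' @export
add_stimulation_pulses <- function(trace, pulse_indices, magnitude) {
  trace <- as_emg_trace(trace)
  pulse_indices <- as.integer(pulse_indices)
  if (any(pulse_indices < 1L) || any(pulse_indices > nrow(trace)))
    stop_parameter("Pulse indices must lie within the trace.")
  v <- trace$value
  v[pulse_indices] <- v[pulse_indices] + magnitude
  retrace(trace, v)
}

#' Saturate samples after each stimulation pulse
#'
#' Emulates amplifier saturation: within a window of `clip_window`
#' samples starting at each pulse, samples exceeding `clip_level` in
#' magnitude are clamped to +/- `clip_level`. At 1000 Hz with 25 Hz
#' stimulation, a 4-sample window affects at most 10% of the 40 samples
#' between pulses.
#'
#' @inheritParams add_stimulation_pulses
#' @param clip_window samples saturated after each pulse (0-4);
#'   0 is the identity.
#' @param clip_level saturation amplitude (non-negative).
#' @return An [emg_trace()].
#' @export
apply_clipping <- function(trace, pulse_indices, clip_window, clip_level) {
  trace <- as_emg_trace(trace)
  if (clip_window < 0 || clip_window > 4)
    stop_parameter("`clip_window` must be between 0 and 4 samples.")
  if (clip_level < 0) stop_parameter("`clip_level` must be non-negative.")
  if (clip_window == 0) return(trace)
  v <- trace$value
  idx <- unique(as.vector(outer(as.integer(pulse_indices),
                                0:(clip_window - 1L), `+`)))
  idx <- idx[idx >= 1L & idx <= length(v)]
  v[idx] <- pmin(pmax(v[idx], -clip_level), clip_level)
  retrace(trace, v)
}

#' Simulate a contaminated EMG recording
#'
#' Generates clean voluntary EMG and contaminates it the way an FES
#' session does: a one-sample stimulation pulse and a stochastic m-wave
#' at every stimulation period, both scaled so that the peak artifact
#' amplitude is `magnitude_ratio` times the clean RMS, plus optional
#' post-pulse saturation. The first pulse falls on the first sample, so
#' the trace is pulse-aligned.
#'
#' @param duration_s recording duration in seconds.
#' @param fs sampling rate in Hz; `fs / params$f_stim` must be integer so
#'   the stimulation period is a whole number of samples.
#' @param params an [artifact_params()].
#' @param vemg_rms RMS amplitude of the clean voluntary EMG.
#' @param seed integer seed (reproducible), or `NULL`.
#' @param band pass-band of the voluntary EMG, in Hz.
#' @return A list of class `fes_recording` with elements `clean`,
#'   `contaminated` (both [emg_trace()]), `pulse_indices` (1-based),
#'   `mwave_params` (tibble) and `params`.
#' @examples
#' rec <- make_recording(2, fs = 1000, seed = 1)
#' length(rec$pulse_indices) # 2 s at 25 Hz = 50 pulses
#' @export
make_recording <- function(duration_s = 35, fs = 1000,
                           params = artifact_params(), vemg_rms = 1,
                           seed = NULL, band = c(20, 450)) {
  period <- fs / params$f_stim
  if (abs(period - round(period)) > 1e-9)
    stop_config("`fs / f_stim` must be an integer number of samples.")
  period <- as.integer(round(period))
  n <- round(duration_s * fs)
  pulse_indices <- seq.int(1L, n, by = period)

  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(seed + c(0L, 1L))
  clean <- generate_vemg(duration_s, fs = fs, band = band, rms = vemg_rms,
                         seed = seeds[[1]])
  mw_par <- sample_mwave_params(params, length(pulse_indices), seed = seeds[[2]])

  if (params$magnitude_ratio == 0 || vemg_rms == 0) {
    contaminated <- retrace(clean, clean$value, label = "contaminated")
    return(structure(list(clean = clean, contaminated = contaminated,
                          pulse_indices = pulse_indices,
                          mwave_params = mw_par, params = params),
                     class = "fes_recording"))
  }

  peak <- params$magnitude_ratio * trace_rms(clean)
  mwave <- generate_mwave_train(fs, pulse_indices, mw_par, n)
  artifact <- mwave$value * (peak / max(abs(mwave$value)))
  artifact[pulse_indices] <- artifact[pulse_indices] + peak
  # m-wave tails from earlier pulses overlap the pulse samples; rescale
  # the combined train so its peak sits exactly at magnitude_ratio x RMS
  artifact <- artifact * (peak / max(abs(artifact)))
  contaminated <- emg_trace(clean$value + artifact,
                            fs = fs, label = "contaminated")
  if (params$clip_window > 0)
    contaminated <- apply_clipping(contaminated, pulse_indices,
                                   params$clip_window, params$clip_level)

  structure(list(clean = clean, contaminated = contaminated,
                 pulse_indices = pulse_indices,
                 mwave_params = mw_par, params = params),
            class = "fes_recording")
}

#' @export
print.fes_recording <- function(x, ...) {
  cat(sprintf(paste0("# Simulated FES recording: %.1f s at %g Hz, %d pulses ",
                     "(%g Hz stimulation), artifact/vEMG ratio %g\n"),
              trace_duration(x$clean), trace_fs(x$clean),
              length(x$pulse_indices), x$params$f_stim,
              x$params$magnitude_ratio))
  invisible(x)
}

#' @export
autoplot.fes_recording <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = object$clean$time, value = object$clean$value,
           signal = "clean vEMG"),
    tibble(time = object$contaminated$time, value = object$contaminated$value,
           signal = "contaminated")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}
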