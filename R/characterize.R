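#' Average the stored per-frame coefficients
#'
#' The adaptive filter refits its coefficients for every frame; its
#' average behaviour over a run is summarized by the elementwise mean of
#' the stored coefficient vectors, which defines a fixed equivalent FIR
#' filter for frequency-domain analysis.
#'
#' @param state an `adaptive_state` with stored coefficient history.
#' @return Numeric vector of length `M`.
#' @export
average_coefficients <- function(state) {
  colMeans(coefficient_matrix(state))
}

#' Equivalent FIR taps of the frame predictor
#'
#' With fixed coefficients `b`, the adaptive subtraction
#' `y(n) = x(n) - sum_i b_i x(n - i L)` is an FIR filter of order `M*L`:
#' tap 0 is 1, tap `i*L` is `-b[i]`, all other taps are 0. With `M = 1`,
#' `b = 1` this reduces to the comb filter with gain -1.
#'
#' @param avg_b coefficient vector of length `M` (typically from
#'   [average_coefficients()]).
#' @param L frame length in samples.
#' @return Numeric tap vector of length `M*L + 1`.
#' @export
equivalent_fir <- function(avg_b, L) {
  if (L < 1 || L != round(L)) stop_parameter("`L` must be a positive integer.")
  M <- length(avg_b)
  taps <- numeric(M * L + 1)
  taps[1] <- 1
  taps[seq_len(M) * L + 1] <- -avg_b
  taps
}

# H(e^{j w}) on a uniform grid of n points over [0, fs/2), via one FFT.
fir_transfer <- function(taps, n_points) {
  nfft <- 2L * n_points
  stats::fft(c(taps, numeric(nfft - length(taps))))[seq_len(n_points)]
}

unwrap_phase <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Frequency response of an FIR filter
#'
#' @param fir numeric tap vector.
#' @param fs sampling rate in Hz.
#' @param n_points number of frequency bins on `[0, fs/2)`; the default
#'   4096 resolves the narrow comb notches.
#' @param floor_db magnitude floor in dB (notch nulls are -Inf).
#' @return A tibble with columns `freq` (Hz), `mag_db`, `phase`
#'   (radians, unwrapped).
#' @export
frequency_response <- function(fir, fs = 1000, n_points = 4096,
                               floor_db = -120) {
  if (n_points < length(fir))
    stop_parameter("`n_points` must be at least the number of taps.")
  H <- fir_transfer(fir, n_points)
  freq <- (seq_len(n_points) - 1) * fs / (2 * n_points)
  mag_db <- pmax(20 * log10(Mod(H)), floor_db)
  tibble(freq = freq, mag_db = mag_db, phase = unwrap_phase(Arg(H)))
}

#' Group delay of an FIR filter
#'
#' Negative derivative of the phase response, computed by the standard
#' ratio-of-transforms formulation `Re(F(k * h) / F(h))`. Bins at the
#' notch nulls, where the phase jumps and the delay is singular, are
#' masked to `NA`.
#'
#' @inheritParams frequency_response
#' @param mask_tol relative magnitude below which a bin counts as a
#'   null and is masked.
#' @return Numeric vector of delays in samples, one per frequency bin.
#' @export
group_delay <- function(fir, fs = 1000, n_points = 4096, mask_tol = 1e-6) {
  H <- fir_transfer(fir, n_points)
  Hr <- fir_transfer((seq_along(fir) - 1) * fir, n_points)
  gd <- Re(Hr / H)
  gd[Mod(H) < mask_tol * max(Mod(H))] <- NA_real_
  gd
}

#' Effective end-to-end delay of the frame-based filter
#'
#' The adaptive filter only produces a frame after recording it in full,
#' adding one frame length `L` to the group delay. The minimum effective
#' delay combines the maximum pass-band group delay with `L`; the
#' maximum combines the overall (near-stop-band) maximum with `L`. The
#' maximum applies mainly to the removed components, so the delay felt
#' by the voluntary EMG is close to the minimum.
#'
#' @param passband_max_delay maximum group delay within the pass band,
#'   in samples.
#' @param stopband_max_delay maximum group delay overall (attained near
#'   the stop bands), in samples.
#' @param L frame length in samples.
#' @param fs sampling rate in Hz.
#' @return A tibble with `min_samples`, `max_samples`, `min_ms`, `max_ms`.
#' @examples
#' effective_delay(9, 73, L = 40)   # 49 ms minimum, 113 ms maximum
#' effective_delay(45, 167, L = 80) # 125 ms minimum, 247 ms maximum
#' @export
effective_delay <- function(passband_max_delay, stopband_max_delay, L,
                            fs = 1000) {
  min_s <- passband_max_delay + L
  max_s <- stopband_max_delay + L
  tibble(min_samples = min_s, max_samples = max_s,
         min_ms = min_s / fs * 1000, max_ms = max_s / fs * 1000)
}

#' Characterize an adaptive filter run
#'
#' Builds the average-coefficient equivalent FIR and its frequency-domain
#' portrait: magnitude and phase response, group delay, the pass-band
#' and stop-band group-delay extrema, and the effective end-to-end delay
#' including the one-frame buffering latency.
#'
#' @param x an `adaptive_state` (from [adaptive_apply()]) or a raw
#'   coefficient vector.
#' @param L frame length in samples; taken from the state when available.
#' @param fs sampling rate in Hz.
#' @param n_points frequency bins on `[0, fs/2)`.
#' @param passband_db magnitude threshold (dB) defining the pass band
#'   for delay reporting; the stop-band extremum is the overall maximum,
#'   attained next to the notches.
#' @return A list of class `filter_response` with elements `avg_b`,
#'   `fir`, `response` (tibble: freq, mag_db, phase, group_delay),
#'   `passband_max_delay`, `stopband_max_delay`, `delay` (tibble from
#'   [effective_delay()]), `L`, `fs`.
#' @export
filter_response <- function(x, L = NULL, fs = 1000, n_points = 4096,
                            passband_db = -3) {
  if (inherits(x, "adaptive_state")) {
    avg_b <- average_coefficients(x)
    L <- L %||% x$config$L
    fs <- x$fs %||% fs
  } else {
    avg_b <- as.numeric(x)
    if (is.null(L)) stop_parameter("`L` is required with a raw coefficient vector.")
  }
  fir <- equivalent_fir(avg_b, L)
  resp <- frequency_response(fir, fs = fs, n_points = n_points)
  resp$group_delay <- group_delay(fir, fs = fs, n_points = n_points)
  ok <- is.finite(resp$group_delay)
  pass <- ok & resp$mag_db >= passband_db
  pb <- if (any(pass)) max(resp$group_delay[pass]) else 0
  # stop bands: the structural notches sit at multiples of fs / L;
  # "near the stop band" = within 2 grid bins of a notch frequency
  notch_freqs <- seq(fs / L, fs / 2, by = fs / L)
  bin_hz <- fs / (2 * n_points)
  near_notch <- ok & purrr::reduce(
    lapply(notch_freqs, function(f0) abs(resp$freq - f0) <= 2 * bin_hz),
    `|`, .init = rep(FALSE, n_points))
  sb <- if (any(near_notch)) max(resp$group_delay[near_notch]) else 0
  overall <- if (any(ok)) max(resp$group_delay[ok]) else 0
  structure(
    list(avg_b = avg_b, fir = fir, response = resp,
         passband_max_delay = pb, stopband_max_delay = sb,
         delay = effective_delay(pb, overall, L = L, fs = fs),
         L = L, fs = fs),
    class = "filter_response"
  )
}

#' @export
print.filter_response <- function(x, ...) {
  cat(sprintf("# Adaptive filter response: M = %d, L = %d, %d taps\n",
              length(x$avg_b), x$L, length(x$fir)))
  cat(sprintf("  group delay: %.1f samples (passband) / %.1f samples (near stopband)\n",
              x$passband_max_delay, x$stopband_max_delay))
  cat(sprintf("  effective delay incl. one-frame buffering: %.1f-%.1f ms\n",
              x$delay$min_ms, x$delay$max_ms))
  invisible(x)
}

#' @param x a `filter_response`.
#' @param ... unused.
#' @rdname filter_response
#' @export
tidy.filter_response <- function(x, ...) x$response

#' @rdname filter_response
#' @export
glance.filter_response <- function(x, ...) {
  tibble(L = x$L, M = length(x$avg_b), fs = x$fs,
         passband_max_delay = x$passband_max_delay,
         stopband_max_delay = x$stopband_max_delay,
         effective_delay_min_ms = x$delay$min_ms,
         effective_delay_max_ms = x$delay$max_ms)
}

#' @param object a `filter_response`.
#' @rdname filter_response
#' @export
autoplot.filter_response <- function(object, ...) {
  df <- tidyr::pivot_longer(object$response, -"freq",
                            names_to = "panel", values_to = "value")
  df$panel <- factor(df$panel, c("mag_db", "phase", "group_delay"),
                     c("magnitude (dB)", "phase (rad)", "group delay (samples)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL)
}

#' Apply a frozen-coefficient frame predictor
#'
#' Direct implementation of `y(n) = x(n) - sum_i b_i x(n - i L)` with a
#' fixed coefficient vector and zero pre-history; equals convolution
#' with [equivalent_fir()]. Used to check that the equivalent FIR
#' faithfully represents the average filter.
#'
#' @param trace an [emg_trace()] or numeric vector.
#' @param b coefficient vector.
#' @param L frame length in samples.
#' @return Numeric vector, same length as the input.
#' @export
apply_frozen_coefficients <- function(trace, b, L) {
  x <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  y <- x
  for (i in seq_along(b)) {
    lag <- i * L
    delayed <- c(numeric(lag), x[seq_len(max(0, length(x) - lag))])
    y <- y - b[i] * delayed
  }
  y
}
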