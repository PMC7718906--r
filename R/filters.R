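#' Comb filter delay
#'
#' The feedforward comb filter cancels a periodic artifact when its
#' delay equals one stimulation period in samples, `L = fs / f_stim`;
#' the filter's transfer-function zeros then align with the stimulation
#' frequency and its harmonics. The ratio must be an integer, otherwise
#' the notches miss the artifact harmonics.
#'
#' @param fs sampling rate in Hz.
#' @param f_stim stimulation frequency in Hz.
#' @return Integer delay `L` in samples.
#' @examples
#' comb_delay(1000, 25) # 40
#' @export
comb_delay <- function(fs, f_stim) {
  if (fs <= 0 || f_stim <= 0) stop_parameter("`fs` and `f_stim` must be positive.")
  L <- fs / f_stim
  if (abs(L - round(L)) > 1e-9)
    stop_config(sprintf(
      "fs / f_stim = %g is not an integer: comb notches would misalign with the artifact harmonics.",
      L))
  as.integer(round(L))
}

#' Comb filter specification
#'
#' @param fs sampling rate in Hz.
#' @param f_stim stimulation frequency in Hz.
#' @param b feedforward gain at the delayed tap; `-1` (the default)
#'   places exact nulls at the stimulation harmonics.
#' @return A list of class `comb_spec` with fields `L`, `b`, `fs`, `f_stim`.
#' @export
comb_spec <- function(fs = 1000, f_stim = 25, b = -1) {
  structure(list(L = comb_delay(fs, f_stim), b = b, fs = fs, f_stim = f_stim),
            class = "comb_spec")
}

#' Apply the feedforward comb filter
#'
#' Computes `y(n) = x(n) + b * x(n - L)` causally, with zero pre-history
#' (the first `L` output samples see zeros in the delayed tap, matching
#' a real-time start). With `b = -1`, any input that is exactly
#' `L`-periodic maps to zero after the first `L` samples.
#'
#' @param trace an [emg_trace()].
#' @param spec a [comb_spec()]; its `fs` must match the trace.
#' @return An [emg_trace()] of the same length.
#' @export
comb_apply <- function(trace, spec = comb_spec(trace_fs(trace))) {
  trace <- as_emg_trace(trace)
  L <- spec$L
  if (L >= nrow(trace))
    stop_parameter("Trace must be longer than the comb delay L.")
  x <- trace$value
  delayed <- c(numeric(L), x[seq_len(length(x) - L)])
  retrace(trace, x + spec$b * delayed)
}

#' Split a trace into consecutive frames
#'
#' Frames are non-overlapping blocks of `L` samples; the first `offset`
#' samples and any trailing partial frame are discarded. For the
#' adaptive filter, frames should be pulse-aligned:
#' `offset = (first_pulse_index - 1) %% L`.
#'
#' @param trace an [emg_trace()] or numeric vector.
#' @param L frame length in samples.
#' @param offset samples to skip before the first frame.
#' @return A numeric matrix with `L` rows, one column per frame, with
#'   attribute `offset`.
#' @export
frame_signal <- function(trace, L, offset = 0) {
  x <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  if (L < 1) stop_parameter("`L` must be at least 1.")
  if (L > length(x)) stop_parameter("`L` exceeds the trace length.")
  if (offset < 0) stop_parameter("`offset` must be non-negative.")
  if (offset > 0) x <- x[-seq_len(offset)]
  n_frames <- length(x) %/% L
  if (n_frames == 0) stop_parameter("No complete frame after the offset.")
  m <- matrix(x[seq_len(n_frames * L)], nrow = L)
  attr(m, "offset") <- as.integer(offset)
  m
}

#' Adaptive filter configuration
#'
#' The frame-based adaptive filter models the current frame as a linear
#' combination of the `M` previous frames,
#' `y(n) = x(n) - sum_i b_i x(n - i L)`, with the coefficients `b`
#' re-estimated for every frame by least squares. Because the artifact
#' repeats (almost) every stimulation period while the voluntary EMG is
#' broadband and unpredictable across frames, the fitted combination
#' captures the artifact and the subtraction leaves the voluntary EMG.
#'
#' @param L frame length in samples: 40 (one 25 Hz stimulation period at
#'   1000 Hz, the "short" filter) or 80 (the "long" filter).
#' @param M number of previous frames used as predictors.
#' @param warmup how to emit the first `M` frames, before enough history
#'   exists to fit: `"passthrough"` (unfiltered, the default) or
#'   `"zero"` (silence; preferable when the output drives a controller).
#' @param regularization ridge constant, scaled by the mean diagonal of
#'   the frame Gram matrix, added before the LU solve so degenerate
#'   (rank-deficient) frame histories remain solvable.
#' @param store_coefficients keep the per-frame coefficient vectors for
#'   later characterization.
#' @return A list of class `adaptive_config`.
#' @export
adaptive_config <- function(L = 40, M = 6, warmup = c("passthrough", "zero"),
                            regularization = 1e-8, store_coefficients = TRUE) {
  warmup <- match.arg(warmup)
  if (L < 1 || L != round(L)) stop_parameter("`L` must be a positive integer.")
  if (M < 1 || M != round(M)) stop_parameter("`M` must be a positive integer.")
  if (regularization < 0) stop_parameter("`regularization` must be non-negative.")
  structure(list(L = as.integer(L), M = as.integer(M), warmup = warmup,
                 regularization = regularization,
                 store_coefficients = isTRUE(store_coefficients)),
            class = "adaptive_config")
}

#' Least-squares frame coefficients
#'
#' Solves `min_b || current - t(prev_frames) %*% b ||^2` through the
#' ridge-regularized normal equations, factorized by LU (base
#' [solve()]). Row `i` of `prev_frames` is the frame `i` frames back, so
#' `b[i]` multiplies `x(n - i L)`.
#'
#' @param current_frame numeric vector of length `L`.
#' @param prev_frames `M x L` numeric matrix of the previous frames.
#' @param regularization ridge constant, scaled by the mean diagonal of
#'   the Gram matrix `prev %*% t(prev)`.
#' @return Numeric coefficient vector of length `M`.
#' @export
solve_frame_coefficients <- function(current_frame, prev_frames,
                                     regularization = 1e-8) {
  if (!is.matrix(prev_frames) || ncol(prev_frames) != length(current_frame))
    stop_parameter("`prev_frames` must be an M x L matrix matching the frame.")
  if (!all(is.finite(current_frame)) || !all(is.finite(prev_frames)))
    stop_data("Frames must be finite.")
  G <- prev_frames %*% t(prev_frames)
  scale <- mean(diag(G))
  lambda <- regularization * if (scale > 0) scale else 1
  rhs <- prev_frames %*% current_frame
  as.vector(solve(G + diag(lambda, nrow(G)), rhs))
}

#' Initialize adaptive filter state
#'
#' State for streaming use: samples can be fed in arbitrary chunks with
#' [adaptive_push()] and the emitted output is bitwise-identical to
#' one-shot processing, because the state carries the pending partial
#' frame and the full frame history.
#'
#' @param config an [adaptive_config()].
#' @param offset samples passed through unfiltered before framing starts
#'   (use `(first_pulse_index - 1) %% L` for pulse alignment).
#' @param fs sampling rate of the stream, in Hz.
#' @return A list of class `adaptive_state`.
#' @export
new_adaptive_state <- function(config = adaptive_config(), offset = 0, fs = 1000) {
  if (offset < 0) stop_parameter("`offset` must be non-negative.")
  structure(
    list(config = config, fs = fs,
         offset = as.integer(offset), leading_remaining = as.integer(offset),
         pending = numeric(0),
         history = matrix(0, nrow = config$M, ncol = config$L),
         n_history = 0L,
         frames_processed = 0L,
         coefficients = list()),
    class = "adaptive_state"
  )
}

#' Stream samples through the adaptive filter
#'
#' @param state an `adaptive_state`.
#' @param samples numeric vector (any length, including 0).
#' @return A list with `state` (updated) and `output` (the samples whose
#'   filtered value is now determined; leading offset samples and, per
#'   warm-up policy, the first `M` frames included).
#' @export
adaptive_push <- function(state, samples) {
  stopifnot(inherits(state, "adaptive_state"))
  samples <- as.numeric(samples)
  cfg <- state$config
  out <- list()

  if (state$leading_remaining > 0L && length(samples) > 0L) {
    k <- min(state$leading_remaining, length(samples))
    out[[length(out) + 1L]] <- samples[seq_len(k)]
    samples <- samples[-seq_len(k)]
    state$leading_remaining <- state$leading_remaining - as.integer(k)
  }

  state$pending <- c(state$pending, samples)
  L <- cfg$L
  while (length(state$pending) >= L) {
    frame <- state$pending[seq_len(L)]
    state$pending <- state$pending[-seq_len(L)]
    if (state$n_history < cfg$M) {
      out[[length(out) + 1L]] <-
        if (cfg$warmup == "passthrough") frame else numeric(L)
    } else {
      b <- solve_frame_coefficients(frame, state$history, cfg$regularization)
      out[[length(out) + 1L]] <- frame - as.vector(crossprod(state$history, b))
      if (cfg$store_coefficients)
        state$coefficients[[length(state$coefficients) + 1L]] <- b
    }
    # newest frame becomes row 1; older frames shift down
    if (cfg$M > 1L)
      state$history <- rbind(matrix(frame, nrow = 1L),
                             state$history[-cfg$M, , drop = FALSE])
    else
      state$history <- matrix(frame, nrow = 1L)
    state$n_history <- min(state$n_history + 1L, cfg$M)
    state$frames_processed <- state$frames_processed + 1L
  }
  list(state = state, output = unlist(out) %||% numeric(0))
}

#' Per-frame coefficient history
#'
#' @param x an `adaptive_state` (or the `state` element of a filter
#'   result).
#' @param ... unused.
#' @return A tibble with one row per (post-warm-up) frame and columns
#'   `frame`, `coefficient` (1..M, lag order in frames) and `value`.
#' @export
tidy.adaptive_state <- function(x, ...) {
  if (length(x$coefficients) == 0)
    return(tibble(frame = integer(), coefficient = integer(), value = numeric()))
  m <- do.call(rbind, x$coefficients)
  tibble(frame = rep(seq_len(nrow(m)), each = ncol(m)),
         coefficient = rep(seq_len(ncol(m)), nrow(m)),
         value = as.vector(t(m)))
}

#' @rdname tidy.adaptive_state
#' @export
glance.adaptive_state <- function(x, ...) {
  tibble(frames_processed = x$frames_processed,
         frames_fitted = length(x$coefficients),
         L = x$config$L, M = x$config$M,
         warmup = x$config$warmup,
         pending_samples = length(x$pending))
}

coefficient_matrix <- function(state) {
  if (length(state$coefficients) == 0)
    stop_state("No stored coefficients: filter has not passed warm-up, or `store_coefficients` was FALSE.")
  do.call(rbind, state$coefficients)
}

#' Apply the adaptive filter to a whole trace
#'
#' One-shot convenience over the streaming interface. The first `offset`
#' samples and any trailing partial frame are passed through unchanged;
#' the first `M` complete frames follow the warm-up policy; every later
#' frame is replaced by its least-squares prediction residual.
#'
#' @param trace an [emg_trace()].
#' @param config an [adaptive_config()].
#' @param offset samples to skip before framing (pulse alignment).
#' @return A list with `trace` (filtered [emg_trace()], same length) and
#'   `state` (final `adaptive_state`, including coefficient history).
#' @examples
#' rec <- make_recording(3, seed = 2)
#' res <- adaptive_apply(rec$contaminated, adaptive_config(L = 40, M = 6))
#' glance(res$state)
#' @export
adaptive_apply <- function(trace, config = adaptive_config(), offset = 0) {
  trace <- as_emg_trace(trace)
  n <- nrow(trace)
  need <- (config$M + 1L) * config$L + offset
  if (n < need)
    stop_data(sprintf("Trace too short: need at least (M+1)*L + offset = %d samples, got %d.",
                      need, n))
  st <- new_adaptive_state(config, offset = offset, fs = trace_fs(trace))
  res <- adaptive_push(st, trace$value)
  out <- c(res$output, res$state$pending) # trailing partial frame passes through
  list(trace = retrace(trace, out), state = res$state)
}

#' Comb + adaptive extraction chain
#'
#' The full software artifact-suppression chain: the comb filter first
#' (optional) to null the stimulation harmonics, then the frame-based
#' adaptive filter to remove the remaining quasi-periodic m-wave. With
#' `use_comb = FALSE` this is exactly [adaptive_apply()].
#'
#' @param trace contaminated [emg_trace()].
#' @param use_comb apply the comb stage first?
#' @param config an [adaptive_config()].
#' @param spec a [comb_spec()]; must share the trace's sampling rate and
#'   imply a frame length commensurate with `config$L`.
#' @param offset pulse-alignment offset in samples.
#' @return A list with `trace` (extracted voluntary-EMG estimate) and
#'   `state` (adaptive filter state).
#' @export
filter_chain <- function(trace, use_comb = TRUE, config = adaptive_config(),
                         spec = comb_spec(trace_fs(trace)), offset = 0) {
  trace <- as_emg_trace(trace)
  if (use_comb) {
    if (abs(spec$fs - trace_fs(trace)) > 1e-9)
      stop_config("Comb spec sampling rate does not match the trace.")
    trace <- comb_apply(trace, spec)
  }
  adaptive_apply(trace, config = config, offset = offset)
}
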