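#' EMG signal traces
#'
#' An `emg_trace` is a tibble with columns `time` (seconds) and `value`
#' (amplitude, microvolt-like units), carrying the sampling rate and a
#' channel label as attributes. All filtering, simulation and scoring
#' functions in the package take and return this type, so pipelines
#' compose with the pipe. The underlying tibble is ordinary: dplyr verbs
#' work on it (they return a plain tibble; use [as_emg_trace()] to
#' restore the class if needed).
#'
#' @param value numeric vector of samples; all values must be finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param label channel name.
#'
#' @return A tibble of class `emg_trace` with columns `time` and `value`.
#' @examples
#' tr <- emg_trace(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs = 1000)
#' trace_fs(tr)
#' @export
emg_trace <- function(value, fs, label = "ch1") {
  value <- as.numeric(value)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_parameter("`fs` must be a positive finite scalar.")
  if (length(value) < 1L)
    stop_parameter("A trace must contain at least one sample.")
  if (!all(is.finite(value)))
    stop_data("Trace samples must all be finite.")
  new_tibble(
    list(time = (seq_along(value) - 1) / fs, value = value),
    fs = as.numeric(fs), label = as.character(label)[1],
    class = "emg_trace"
  )
}

#' Coerce to an EMG trace
#'
#' @param x an `emg_trace`, a numeric vector, or a data frame with a
#'   `value` column.
#' @param fs sampling rate in Hz; required unless `x` already carries one.
#' @param label channel name; defaults to the existing label or `"ch1"`.
#' @return An `emg_trace`.
#' @export
as_emg_trace <- function(x, fs = NULL, label = NULL) {
  if (inherits(x, "emg_trace") && is.null(fs) && is.null(label)) return(x)
  if (is.data.frame(x)) {
    if (is.null(fs)) fs <- attr(x, "fs")
    if (is.null(label)) label <- attr(x, "label") %||% "ch1"
    if (!"value" %in% names(x))
      stop_parameter("Data-frame input must have a `value` column.")
    x <- x$value
  }
  if (is.null(fs)) stop_parameter("`fs` is required for vector input.")
  emg_trace(as.numeric(x), fs = fs, label = label %||% "ch1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname emg_trace
#' @param x an `emg_trace`.
#' @export
trace_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop_parameter("Not an emg_trace: no sampling rate attribute.")
  fs
}

#' @rdname emg_trace
#' @export
trace_label <- function(x) attr(x, "label") %||% "ch1"

#' @rdname emg_trace
#' @export
trace_duration <- function(x) nrow(x) / trace_fs(x)

# Rebuild a trace with new samples, keeping rate and (optionally) label.
retrace <- function(template, value, label = trace_label(template)) {
  emg_trace(value, fs = trace_fs(template), label = label)
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("# EMG trace '%s': %d samples at %g Hz (%.3f s)\n",
              trace_label(x), nrow(x), trace_fs(x), trace_duration(x)))
  NextMethod()
}

#' Root-mean-square amplitude of a trace
#' @param trace an `emg_trace` or numeric vector.
#' @return RMS amplitude (scalar).
#' @export
trace_rms <- function(trace) {
  v <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  sqrt(mean(v^2))
}

#' Line plot of one or more traces
#'
#' @param object an `emg_trace`.
#' @param ... further traces to overlay, named or not.
#' @return A ggplot object.
#' @export
autoplot.emg_trace <- function(object, ...) {
  extra <- list(...)
  traces <- c(list(object), extra[vapply(extra, inherits, TRUE, "emg_trace")])
  df <- purrr::map_dfr(traces, function(tr)
    tibble(time = tr$time, value = tr$value, channel = trace_label(tr)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value, colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude", colour = NULL)
}
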