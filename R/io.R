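#' Write a signal trace to a delimited text file
#'
#' Plain-text format: `#`-prefixed header lines (`fs`, `label`, optional
#' comma-separated 1-based `pulses`), a column-name line, then two
#' space-separated columns `time value` at full double precision, so a
#' write/read round trip is lossless.
#'
#' @param trace an [emg_trace()].
#' @param path output file.
#' @param pulse_indices optional 1-based stimulation pulse indices
#'   stored in the header.
#' @return `path`, invisibly.
#' @export
write_signal <- function(trace, path, pulse_indices = NULL) {
  trace <- as_emg_trace(trace)
  header <- c(sprintf("# fs: %.17g", trace_fs(trace)),
              sprintf("# label: %s", trace_label(trace)))
  if (!is.null(pulse_indices))
    header <- c(header, sprintf("# pulses: %s",
                                paste(as.integer(pulse_indices), collapse = ",")))
  body <- sprintf("%.17g %.17g", trace$time, trace$value)
  writeLines(c(header, "time value", body), path)
  invisible(path)
}

#' Read a signal trace written by [write_signal()]
#'
#' @param path input file.
#' @return An [emg_trace()]; any stored pulse indices are attached as
#'   attribute `pulse_indices`.
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("No such file: %s", path))
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  header <- lines[is_header]
  get_field <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), header, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(sprintf("^#\\s*%s:\\s*", key), "", hit[1])
  }
  fs <- get_field("fs")
  if (is.null(fs))
    stop_format(sprintf("%s: missing required `# fs:` header line.", path))
  fs <- as.numeric(fs)
  label <- get_field("label") %||% "ch1"
  pulses <- get_field("pulses")

  body <- lines[!is_header]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop_format(sprintf("%s: no data rows.", path))
  body <- body[-1] # column-name line
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0)
    stop_format(sprintf("%s: malformed data row at line %d.",
                        path, sum(is_header) + 1 + bad[1]))
  value <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (anyNA(value))
    stop_format(sprintf("%s: non-numeric value at data row %d.",
                        path, which(is.na(value))[1]))
  tr <- emg_trace(value, fs = fs, label = label)
  if (!is.null(pulses))
    attr(tr, "pulse_indices") <- as.integer(strsplit(pulses, ",")[[1]])
  tr
}

#' Write/read a per-frame coefficient history
#'
#' One row of `M` space-separated coefficients per frame.
#'
#' @param state an `adaptive_state` (or a coefficient matrix).
#' @param path file path.
#' @return `path` invisibly / a numeric matrix with one row per frame.
#' @export
write_coefficients <- function(state, path) {
  m <- if (is.matrix(state)) state else coefficient_matrix(state)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("No such file: %s", path))
  as.matrix(utils::read.table(path, header = FALSE))
}
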