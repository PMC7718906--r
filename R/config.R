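run_config_defaults <- function() {
  list(seed = 1L, fs = 1000, f_stim = 25, duration_s = 35,
       vemg_rms = 1, band_low = 20, band_high = 450,
       alpha_mean = 200, alpha_halfrange = 20,
       tau_mean = 20, tau_halfrange = 5,
       magnitude_ratio = 100, clip_window = 0, clip_level = Inf,
       frame_length = 40, history = 6, use_comb = TRUE,
       segment_len = 1024,
       eta = 0.1, pw_min = 50, pw_max = 300, current_mA = 20,
       power_window_ms = 200, threshold = 0.2,
       threshold_mode = "single", mutual_exclusion = TRUE)
}

#' Load a run configuration
#'
#' Reads a `key = value` text file (or `key: value`; `#` starts a
#' comment) and merges it over the default operating point: 1000 Hz EMG,
#' 25 Hz stimulation, frame length 40 with 6 history frames, a 35 s
#' study, worst-case 100x artifacts, and the standard controller
#' settings. Unknown keys are rejected; cross-field invariants
#' (integer `fs / f_stim`, valid frame length) are validated.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_format(sprintf("No such file: %s", path))
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "\\s*[=:]\\s*")[[1]]
      if (length(kv) != 2)
        stop_format(sprintf("Malformed config line: '%s'", ln))
      key <- kv[1]
      if (!key %in% names(cfg))
        stop_config(sprintf("Unknown config key: '%s'", key))
      old <- cfg[[key]]
      cfg[[key]] <- if (is.character(old)) kv[2]
      else if (is.logical(old)) as.logical(kv[2])
      else as.numeric(kv[2])
      if (is.na(cfg[[key]]))
        stop_config(sprintf("Invalid value for config key '%s': '%s'", key, kv[2]))
    }
  }
  ratio <- cfg$fs / cfg$f_stim
  if (abs(ratio - round(ratio)) > 1e-9)
    stop_config(sprintf("fs / f_stim = %g is not an integer.", ratio))
  if (cfg$frame_length < 1 || cfg$frame_length != round(cfg$frame_length))
    stop_config("`frame_length` must be a positive integer.")
  if (!cfg$threshold_mode %in% c("single", "double"))
    stop_config("`threshold_mode` must be 'single' or 'double'.")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop_config("`threshold` must be in (0, 1).")
  structure(cfg, class = "run_config")
}

#' Artifact parameters from a run configuration
#' @param cfg a [load_config()] result.
#' @return An [artifact_params()].
#' @export
config_artifact_params <- function(cfg) {
  artifact_params(f_stim = cfg$f_stim,
                  alpha_mean = cfg$alpha_mean, alpha_halfrange = cfg$alpha_halfrange,
                  tau_mean = cfg$tau_mean, tau_halfrange = cfg$tau_halfrange,
                  magnitude_ratio = cfg$magnitude_ratio,
                  clip_window = cfg$clip_window, clip_level = cfg$clip_level)
}

#' Controller configuration from a run configuration
#' @param cfg a [load_config()] result.
#' @return A [control_config()].
#' @export
config_control <- function(cfg) {
  control_config(fs = cfg$fs, f_stim = cfg$f_stim, eta = cfg$eta,
                 pw_min = cfg$pw_min, pw_max = cfg$pw_max,
                 current_mA = cfg$current_mA,
                 power_window_ms = cfg$power_window_ms,
                 threshold_mode = cfg$threshold_mode,
                 mutual_exclusion = cfg$mutual_exclusion)
}
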