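# Analysis configuration: the fixed constants of the pipeline with
# their field-standard defaults, loadable from JSON or YAML.

#' Default analysis configuration
#'
#' Returns the full configuration used by the pipeline.  Every
#' threshold has the value used throughout the analyses: theta
#' criterion 4.5 on the theta/delta ratio, artifact multiplier 2 on the
#' mean trial range, a 1 Hz stimulation band (half-width 0.5 Hz),
#' 1 s / 0.1 s spectrogram windows, encoding exclusion bound of 20 DI
#' points, investigation minima of 3 s (object tasks) and 2 s (odor
#' task), and 10 pA postsynaptic-current criteria.
#'
#' @param ... Named overrides for any default key.  Unknown keys are an
#'   error so that typos cannot silently disable a rule.
#' @return A named list of class `analysis_config`.
#' @examples
#' cfg <- analysis_config(nw = 4)
#' cfg$nw
#' @export
analysis_config <- function(...) {
  defaults <- list(
    # multitaper settings for general spectra / spectrograms
    nw = 3,
    k = 5,
    pad = NULL,
    # band-matched tapers for the 1 Hz stimulation band on 3 s windows
    stim_nw = 1.5,
    stim_k = 2,
    # bands (Hz)
    theta_band = c(5, 12),
    delta_band = c(1, 3),
    stim_halfwidth = 0.5,
    # state + QC criteria
    theta_criterion = 4.5,
    artifact_multiplier = 2,
    # spectrogram
    spectrogram_window = 1,
    spectrogram_step = 0.1,
    # trial windows (s)
    pre = 3,
    during = 3,
    # behavior
    di_exclusion = 20,
    min_investigation_object = 3,
    min_investigation_odor = 2,
    # postsynaptic currents
    psc_criterion_pa = 10,
    gabaa_window_ms = c(0, 50),
    gabab_window_ms = c(50, 400),
    psc_baseline_ms = 50,
    seed = NULL
  )
  overrides <- list(...)
  .merge_config(defaults, overrides)
}

.merge_config <- function(defaults, overrides) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = c("analysis_config", "list"))
}

#' Load an analysis configuration from JSON or YAML
#'
#' Keys present in the file override the defaults of
#' [analysis_config()]; absent keys keep their defaults; unknown keys
#' are an error.  An empty file yields the full default configuration.
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @return An `analysis_config` list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (!nzchar(trimws(txt))) {
    list()
  } else if (ext == "json") {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    yaml::yaml.load(txt)
  }
  if (is.null(vals)) vals <- list()
  .merge_config(analysis_config(), vals)
}

#' Stable hash of an effective configuration
#'
#' Short deterministic digest embedded in result tables so that outputs
#' can be traced to the configuration that produced them.
#'
#' @param config An `analysis_config` list.
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  ser <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                          null = "null")
  # polynomial rolling hash over the serialised bytes; stable across runs
  bytes <- utf8ToInt(as.character(ser))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
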