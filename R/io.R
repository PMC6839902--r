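# On-disk formats: delimited-text sample series and sweeps with JSON
# metadata sidecars, bout tables, and lossless round trips.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read an LFP recording
#'
#' The data file holds one sample per line (µV); the JSON sidecar
#' holds `sampling_rate`, `animal_id`, `genotype`, `location`, and
#' `units`.
#'
#' @param rec An [lfp_recording()].
#' @param path Data-file path; the sidecar is written next to it with
#'   a `.json` extension.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `lfp_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  writeLines(sprintf("%.17g", rec$samples), path)
  meta <- list(sampling_rate = rec$fs, animal_id = rec$animal_id,
               genotype = rec$genotype, location = rec$location,
               units = rec$units)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- .sidecar_path(path)
  if (!file.exists(path)) stop(sprintf("data file not found: %s", path))
  if (!file.exists(sidecar)) stop(sprintf("sidecar not found: %s", sidecar))
  meta <- jsonlite::fromJSON(sidecar)
  for (field in c("sampling_rate", "animal_id", "genotype", "location")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("sidecar %s is missing required field '%s'", sidecar, field))
    }
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("data file %s is empty", path))
  samples <- suppressWarnings(as.numeric(lines))
  if (anyNA(samples)) {
    stop(sprintf("non-numeric sample at line %d of %s",
                 which(is.na(samples))[1], path))
  }
  lfp_recording(samples, meta$sampling_rate, meta$animal_id,
                meta$genotype, meta$location)
}

#' Write / read an event schedule
#'
#' Event schedules are JSON lists of light-onset seconds and
#' stimulation frequency.
#'
#' @param events A data frame with columns `trial`, `onset`,
#'   `frequency`.
#' @param path JSON file path.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset", "frequency") %in% names(events)))
  jsonlite::write_json(as.data.frame(events), path, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' Write / read a current-clamp sweep
#'
#' Three-column tab-delimited text (time s, membrane potential mV,
#' command current pA) with a JSON sidecar (`sampling_rate`,
#' `step_onset`, `step_offset`).
#'
#' @param sweep A `sweep` tibble ([new_sweep()]).
#' @param path Data-file path.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep"))
  utils::write.table(as.data.frame(sweep)[, c("t", "v", "i_cmd")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(sampling_rate = .sweep_fs(sweep),
               step_onset = attr(sweep, "step_onset"),
               step_offset = attr(sweep, "step_offset"))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) stop(sprintf("sidecar not found: %s", sidecar))
  meta <- jsonlite::fromJSON(sidecar)
  for (field in c("sampling_rate", "step_onset", "step_offset")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("sidecar %s is missing required field '%s'", sidecar, field))
    }
  }
  d <- utils::read.table(path, sep = "\t", col.names = c("t", "v", "i_cmd"))
  new_sweep(d$t, d$v, d$i_cmd, meta$sampling_rate, meta$step_onset,
            meta$step_offset)
}

#' Write / read a behavioral bout table
#'
#' CSV with columns `phase`, `object`, `start`, `duration`, plus a JSON
#' sidecar (`animal_id`, `genotype`, `task`).
#'
#' @param sessions A list with `encoding` and `retrieval`
#'   [session_record()]s.
#' @param path CSV path.
#' @export
write_bouts <- function(sessions, path) {
  rows <- dplyr::bind_rows(lapply(c("encoding", "retrieval"), function(ph) {
    s <- sessions[[ph]]
    tibble::tibble(phase = ph, object = s$object, start = s$start,
                   duration = s$duration)
  }))
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  enc <- sessions$encoding
  meta <- list(animal_id = attr(enc, "animal_id"),
               genotype = attr(enc, "genotype"),
               task = attr(enc, "task"))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bouts
#' @export
read_bouts <- function(path) {
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) stop(sprintf("sidecar not found: %s", sidecar))
  meta <- jsonlite::fromJSON(sidecar)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(c("encoding", "retrieval"), function(ph) {
    session_record(d[d$phase == ph, c("object", "start", "duration")],
                   meta$animal_id, meta$genotype, meta$task, ph)
  })
  names(out) <- c("encoding", "retrieval")
  out
}
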