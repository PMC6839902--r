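# Recognition-memory scoring: the discrimination index, animal
# exclusion rules, pulse-train bookkeeping, and per-genotype summary
# tables.

#' Discrimination index
#'
#' `100 * (novel - familiar) / (novel + familiar)` investigation time.
#' Positive values indicate novelty preference; the index is bounded in
#' `[-100, 100]`.
#'
#' @param novel_time,familiar_time Investigation times in seconds
#'   (non-negative).
#' @return The DI, or flagged `NA` when total investigation is zero.
#' @examples
#' discrimination_index(6, 4) # 20
#' @export
discrimination_index <- function(novel_time, familiar_time) {
  stopifnot(novel_time >= 0, familiar_time >= 0)
  total <- novel_time + familiar_time
  if (total == 0) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  100 * (novel_time - familiar_time) / total
}

#' Construct a behavioral session record
#'
#' @param bouts A data frame with columns `object`
#'   (`"novel"`/`"familiar"`), `start` (s), `duration` (s, positive).
#' @param animal_id,genotype Metadata.
#' @param task One of `"OLM"`, `"ORM"`, `"OdorRM"`.
#' @param phase `"encoding"` or `"retrieval"`.
#' @return A tibble of class `session_record` with the metadata as
#'   attributes.
#' @export
session_record <- function(bouts, animal_id, genotype, task, phase) {
  task <- match.arg(task, c("OLM", "ORM", "OdorRM"))
  phase <- match.arg(phase, c("encoding", "retrieval"))
  bouts <- tibble::as_tibble(bouts)
  stopifnot(all(c("object", "start", "duration") %in% names(bouts)))
  stopifnot(all(bouts$duration > 0),
            all(bouts$object %in% c("novel", "familiar")))
  out <- bouts
  class(out) <- c("session_record", class(out))
  attr(out, "animal_id") <- animal_id
  attr(out, "genotype") <- genotype
  attr(out, "task") <- task
  attr(out, "phase") <- phase
  out
}

#' Score a session: DI, total time, bout count
#'
#' Bout durations are summed per object before the index is formed.
#'
#' @param session A [session_record()].
#' @return A one-row tibble of class `di_result`: `animal_id`,
#'   `genotype`, `task`, `phase`, `di`, `total_time`, `n_bouts`,
#'   `scorable`.
#' @export
score_session <- function(session) {
  novel <- sum(session$duration[session$object == "novel"])
  familiar <- sum(session$duration[session$object == "familiar"])
  di <- discrimination_index(novel, familiar)
  out <- tibble::tibble(
    animal_id = attr(session, "animal_id"),
    genotype = attr(session, "genotype"),
    task = attr(session, "task"),
    phase = attr(session, "phase"),
    di = as.numeric(di),
    total_time = novel + familiar,
    n_bouts = nrow(session),
    scorable = !is.na(di)
  )
  class(out) <- c("di_result", class(out))
  out
}

#' Apply the animal exclusion rules
#'
#' An animal/task is excluded when the encoding-day DI magnitude
#' strictly exceeds `di_bound`, or when total investigation in either
#' phase falls below the task-specific minimum (object tasks: 3 s;
#' odor task: 2 s).
#'
#' @param sessions A data frame of scored sessions ([score_session()]
#'   rows) containing both phases for each `animal_id` x `task`.
#' @param di_bound Encoding DI bound (default 20; strict inequality).
#' @param min_object,min_odor Minimum total investigation in seconds
#'   for OLM/ORM and OdorRM respectively.
#' @return A tibble with one row per animal x task: `excluded` and a
#'   comma-separated `reasons` column (`encoding-DI`,
#'   `low-investigation`).
#' @export
apply_exclusions <- function(sessions, di_bound = 20, min_object = 3,
                             min_odor = 2) {
  sessions <- tibble::as_tibble(sessions)
  needed <- c("animal_id", "task", "phase", "di", "total_time")
  stopifnot(all(needed %in% names(sessions)))
  sessions |>
    dplyr::group_by(.data$animal_id, .data$task) |>
    dplyr::group_modify(function(d, key) {
      if (!all(c("encoding", "retrieval") %in% d$phase)) {
        stop(sprintf(
          "animal %s, task %s: both encoding and retrieval phases are required",
          key$animal_id, key$task
        ))
      }
      enc <- d[d$phase == "encoding", ]
      minimum <- if (key$task == "OdorRM") min_odor else min_object
      reasons <- character(0)
      if (!is.na(enc$di) && abs(enc$di) > di_bound) {
        reasons <- c(reasons, "encoding-DI")
      }
      if (any(d$total_time < minimum)) {
        reasons <- c(reasons, "low-investigation")
      }
      tibble::tibble(
        excluded = length(reasons) > 0,
        reasons = paste(reasons, collapse = ",")
      )
    }) |>
    dplyr::ungroup()
}

#' Pulse-train schedule and duty cycle
#'
#' Onset times of light pulses within each epoch of a session, and the
#' train's duty cycle `100 * on / (on + off)`.
#'
#' @param on,off Pulse on and off times in seconds.
#' @param epoch Epoch (train) duration in seconds.
#' @param inter_epoch Interval between epoch onsets in seconds.
#' @param session Total session duration in seconds.
#' @return A list: `pulses` (tibble: epoch, onset s),
#'   `pulses_per_epoch`, `duty_cycle` (percent), `period` (s).
#' @examples
#' pulse_train_schedule(0.05, 0.1, 3, 30, 300)$duty_cycle # 33.33
#' @export
pulse_train_schedule <- function(on, off, epoch, inter_epoch, session) {
  stopifnot(on > 0, off > 0, epoch <= inter_epoch)
  period <- on + off
  if (epoch < period) {
    stop(sprintf("epoch of %g s is shorter than one pulse period (%g s)",
                 epoch, period))
  }
  per_epoch <- floor(epoch / period + 1e-9)
  epoch_onsets <- seq(0, session - epoch, by = inter_epoch)
  pulses <- tidyr::expand_grid(
    epoch_onset = epoch_onsets,
    k = seq_len(per_epoch) - 1
  ) |>
    dplyr::transmute(
      epoch = match(.data$epoch_onset, epoch_onsets),
      onset = .data$epoch_onset + .data$k * period
    )
  list(
    pulses = pulses,
    pulses_per_epoch = per_epoch,
    duty_cycle = 100 * on / (on + off),
    period = period
  )
}

#' Per-genotype and task summary of discrimination indices
#'
#' Excluded animals are omitted; each group reports mean, standard
#' deviation, standard error, n, and mean total investigation.
#'
#' @param results Scored retrieval sessions ([score_session()] rows).
#' @param exclusions Output of [apply_exclusions()].
#' @return A tibble, one row per genotype x task.
#' @export
behavior_summary <- function(results, exclusions) {
  results <- tibble::as_tibble(results)
  keep <- exclusions[!exclusions$excluded, c("animal_id", "task")]
  included <- dplyr::inner_join(results, keep, by = c("animal_id", "task"))
  included <- included[included$phase == "retrieval", ]
  if (!nrow(included)) stop("all animals excluded; nothing to summarise")
  included |>
    dplyr::group_by(.data$genotype, .data$task) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_di = mean(.data$di),
      sd_di = stats::sd(.data$di),
      sem_di = stats::sd(.data$di) / sqrt(dplyr::n()),
      mean_total_time = mean(.data$total_time),
      .groups = "drop"
    )
}
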