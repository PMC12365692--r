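#' Describe an fMRI acquisition design
#'
#' Bundles the scan-design constants every duration computation needs: the
#' repetition time, the number of usable (post-dummy) volumes per run, and
#' how runs nest in conditions and sessions. The default reproduces a
#' multi-session passive-viewing design: TR = 2 s, 205 volumes per run,
#' 2 runs per condition, 3 viewing conditions, 4 sessions.
#'
#' @param tr_seconds Repetition time in seconds.
#' @param volumes_per_run Usable volumes acquired per run (dummies excluded).
#' @param runs_per_condition Runs of each condition within one session.
#' @param n_sessions Number of scan sessions.
#' @param conditions Character vector of unique condition names, in
#'   acquisition order.
#' @return An object of class `acquisition_spec`.
#' @examples
#' acq <- acquisition_spec()
#' total_volumes(acq)            # 4920 volumes per subject
#' session_minutes(acq)          # 41 minutes of functional data per session
#' @export
acquisition_spec <- function(tr_seconds = 2,
                             volumes_per_run = 205,
                             runs_per_condition = 2,
                             n_sessions = 4,
                             conditions = c("non_narrative", "narrative",
                                            "low_demand")) {
  check_scalar_positive(tr_seconds, "tr_seconds")
  volumes_per_run <- check_count(volumes_per_run, "volumes_per_run")
  runs_per_condition <- check_count(runs_per_condition, "runs_per_condition")
  n_sessions <- check_count(n_sessions, "n_sessions")
  if (!is.character(conditions) || length(conditions) < 1L ||
      anyDuplicated(conditions))
    stop_invalid("`conditions` must be unique, non-empty condition names")
  structure(
    list(tr_seconds = tr_seconds,
         volumes_per_run = volumes_per_run,
         runs_per_condition = runs_per_condition,
         n_sessions = n_sessions,
         conditions = conditions),
    class = "acquisition_spec")
}

#' @rdname acquisition_spec
#' @param acq An `acquisition_spec`.
#' @export
total_volumes <- function(acq) {
  acq$volumes_per_run * acq$runs_per_condition * length(acq$conditions) *
    acq$n_sessions
}

#' Volumes collected for one condition across all sessions
#'
#' The denominator of condition-wise retention percentages: volumes per run
#' times runs per condition times sessions (1,640 for the default design).
#'
#' @param acq An `acquisition_spec`.
#' @export
condition_volumes <- function(acq) {
  acq$volumes_per_run * acq$runs_per_condition * acq$n_sessions
}

#' @rdname acquisition_spec
#' @export
session_minutes <- function(acq) {
  volumes_to_minutes(
    acq$volumes_per_run * acq$runs_per_condition * length(acq$conditions),
    acq$tr_seconds)
}

#' Convert between scan minutes and volume counts
#'
#' `minutes_to_volumes()` returns the whole number of volumes that fit in
#' the given time (floor); `volumes_to_minutes()` is its exact inverse on
#' whole volumes. At TR = 2 s, 48 minutes is 1,440 volumes.
#'
#' @param minutes Nonnegative scan duration in minutes.
#' @param volumes Nonnegative volume count.
#' @param tr_seconds Repetition time in seconds.
#' @return An integer volume count / duration in minutes.
#' @examples
#' minutes_to_volumes(48, 2)   # 1440
#' volumes_to_minutes(1440, 2) # 48
#' @export
minutes_to_volumes <- function(minutes, tr_seconds) {
  check_scalar_nonneg(minutes, "minutes")
  check_scalar_positive(tr_seconds, "tr_seconds")
  as.integer(floor(60 * minutes / tr_seconds + 1e-9))
}

#' @rdname minutes_to_volumes
#' @export
volumes_to_minutes <- function(volumes, tr_seconds) {
  check_scalar_nonneg(volumes, "volumes")
  check_scalar_positive(tr_seconds, "tr_seconds")
  volumes * tr_seconds / 60
}
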