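#' Head-motion parameter handling, framewise displacement, and censoring
#'
#' Motion parameters are represented as a numeric matrix with one row per
#' volume and the six rigid-body columns `trans_x, trans_y, trans_z`
#' (mm) and `rot_x, rot_y, rot_z` (radians), sampled once per TR.
#' @name motion
NULL

MOTION_AXES <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

check_motion_params <- function(params) {
  if (is.data.frame(params)) params <- as.matrix(params)
  if (!is.matrix(params) || ncol(params) != 6L)
    stop_invalid("motion parameters must be a volumes x 6 matrix")
  if (!all(is.finite(params)))
    stop_invalid("motion parameters must be finite")
  if (is.null(colnames(params))) colnames(params) <- MOTION_AXES
  params
}

#' Low-pass filter selected motion parameters
#'
#' Removes high-frequency (pseudo-)motion — typically respiration aliased
#' into the phase-encoding direction — with a zero-phase order-4 Butterworth
#' low-pass filter. Only the selected axes are filtered; the rest pass
#' through untouched. The default filters the anterior-posterior translation
#' (`trans_y`) below 0.1 Hz.
#'
#' @param params Volumes x 6 motion-parameter matrix (see [motion]).
#' @param tr_seconds Sampling interval (the TR), seconds.
#' @param cutoff_hz Low-pass cutoff in Hz; must be below Nyquist
#'   (`1 / (2 * tr_seconds)`).
#' @param axes Character vector naming the columns to filter.
#' @param order Butterworth order (applied forward and backward, so the
#'   effective order is doubled).
#' @return Filtered matrix, same dimensions.
#' @export
filter_motion_params <- function(params, tr_seconds = 2, cutoff_hz = 0.1,
                                 axes = "trans_y", order = 4) {
  params <- check_motion_params(params)
  check_scalar_positive(cutoff_hz, "cutoff_hz")
  check_scalar_positive(tr_seconds, "tr_seconds")
  nyquist <- 1 / (2 * tr_seconds)
  if (cutoff_hz >= nyquist)
    stop_invalid("cutoff (%g Hz) must be below Nyquist (%g Hz)",
                 cutoff_hz, nyquist)
  bad <- setdiff(axes, colnames(params))
  if (length(bad))
    stop_invalid("unknown motion axes: %s", paste(bad, collapse = ", "))
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  out <- params
  for (ax in axes) {
    # demean before filtering to avoid start-up transients on the DC level
    mu <- mean(params[, ax])
    out[, ax] <- signal::filtfilt(bf, params[, ax] - mu) + mu
  }
  out
}

#' Framewise displacement from motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations converted to arc length on a
#' sphere (default radius 50 mm). The first volume has no predecessor and
#' is assigned FD = 0.
#'
#' @param params Volumes x 6 motion-parameter matrix (see [motion]).
#' @param head_radius_mm Sphere radius used to convert radians to mm.
#' @return Numeric vector of per-volume FD (mm), first entry 0.
#' @export
compute_fd <- function(params, head_radius_mm = 50) {
  params <- check_motion_params(params)
  check_scalar_positive(head_radius_mm, "head_radius_mm")
  if (nrow(params) < 1L) stop_invalid("need at least one volume")
  if (nrow(params) == 1L) return(0)
  d <- abs(diff(params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Convert rotation columns from degrees to radians
#'
#' @param params Volumes x 6 motion-parameter matrix with rotations in
#'   degrees.
#' @return Matrix with rotations in radians.
#' @export
rotations_deg_to_rad <- function(params) {
  params <- check_motion_params(params)
  params[, 4:6] <- params[, 4:6] * pi / 180
  params
}

#' Censor volumes by framewise displacement
#'
#' Flags each volume as retained (`TRUE`) when its FD does not exceed the
#' threshold. The boundary rule is strict: FD above the threshold is
#' censored, FD exactly at the threshold is retained.
#'
#' @param fd Numeric FD trace (mm), one value per volume.
#' @param threshold_mm Censoring threshold; the conventional value is
#'   0.15 mm.
#' @return A `censor_mask`: logical vector with attributes `threshold_mm`
#'   and `retained` (count of retained volumes).
#' @export
censor <- function(fd, threshold_mm = 0.15) {
  if (!is.numeric(fd) || length(fd) < 1L || any(!is.finite(fd)) ||
      any(fd < 0))
    stop_invalid("`fd` must be a nonnegative finite numeric vector")
  check_scalar_positive(threshold_mm, "threshold_mm")
  mask <- fd <= threshold_mm
  structure(mask, threshold_mm = threshold_mm, retained = sum(mask),
            class = c("censor_mask", "logical"))
}

#' Percentage of collected volumes retained after censoring
#'
#' @param mask Logical censor mask (retained = `TRUE`), or a retained count.
#' @param total_collected Total volumes collected for the same unit
#'   (e.g., 1,640 per condition across four sessions in the default design).
#' @return Percentage in `[0, 100]`.
#' @export
retention_percent <- function(mask, total_collected) {
  retained <- if (is.logical(mask)) sum(mask) else mask
  if (!is.numeric(total_collected) || total_collected <= 0)
    stop_invalid("`total_collected` must be positive")
  if (retained > total_collected)
    stop_invalid("retained (%d) exceeds collected (%d)",
                 retained, total_collected)
  100 * retained / total_collected
}

#' Acquisition time needed to accumulate a post-censored target duration
#'
#' Walks the concatenated censor masks in acquisition order and returns the
#' wall-clock scan time (volumes scanned x TR) at which the cumulative
#' retained volumes first reach the target post-censored duration. With no
#' censoring this equals the target itself; heavier censoring pushes it up.
#'
#' @param masks A logical vector or list of per-run logical masks, in
#'   acquisition order.
#' @param target_minutes Post-censored duration to accumulate, minutes.
#' @param tr_seconds Repetition time, seconds.
#' @return Acquisition minutes, or `NA` (with attribute
#'   `reason = "insufficient data"`) if the target is unreachable.
#' @export
pre_censored_time_to_reach <- function(masks, target_minutes, tr_seconds = 2) {
  if (is.list(masks)) masks <- unlist(masks, use.names = FALSE)
  if (!is.logical(masks)) stop_invalid("`masks` must be logical")
  check_scalar_positive(target_minutes, "target_minutes")
  target_vols <- minutes_to_volumes(target_minutes, tr_seconds)
  if (target_vols == 0L) return(0)
  cum <- cumsum(masks)
  if (cum[length(cum)] < target_vols)
    return(structure(NA_real_, reason = "insufficient data"))
  idx <- which(cum >= target_vols)[1L]
  volumes_to_minutes(idx, tr_seconds)
}

#' Read a confounds table
#'
#' Reads a tab-separated confounds file with either the six motion columns
#' (`trans_x ... rot_z`) or a precomputed `framewise_displacement` column.
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_confounds <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE)
}

#' Summarize retention per subject and condition
#'
#' @param runs List of `parcellated_ts` runs (see [generate_run]).
#' @param masks List of censor masks, parallel to `runs`.
#' @param acq The `acquisition_spec` describing the design.
#' @return Data frame with one row per subject x condition: volumes
#'   collected, retained, and the retention percentage.
#' @export
retention_summary <- function(runs, masks, acq) {
  stopifnot(length(runs) == length(masks))
  key <- vapply(runs, function(r)
    paste(r$subject_id, r$condition, sep = "\r"), character(1))
  retained <- vapply(masks, sum, numeric(1))
  agg <- tapply(retained, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(
    subject_id = vapply(parts, `[`, character(1), 1L),
    condition = vapply(parts, `[`, character(1), 2L),
    collected = condition_volumes(acq),
    retained = as.integer(agg),
    percent = as.numeric(retention_percent_vec(agg, condition_volumes(acq))),
    row.names = NULL, stringsAsFactors = FALSE)
}

retention_percent_vec <- function(retained, total) 100 * retained / total
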