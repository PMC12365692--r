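#' Post-censored volume counts per subject
#'
#' Sums retained volumes over all of a subject's runs — the quantity whose
#' age-group distributions define the motion-group threshold.
#'
#' @param masks_by_subject Named list: subject id -> list of logical
#'   censor masks (one per run).
#' @param expected_runs Optional expected run count per subject; subjects
#'   with fewer runs are flagged with a warning and attribute `partial`.
#' @return Named integer vector of retained volume counts.
#' @export
postcensored_counts <- function(masks_by_subject, expected_runs = NULL) {
  counts <- vapply(masks_by_subject, function(ms) {
    if (is.logical(ms)) sum(ms) else sum(vapply(ms, sum, numeric(1)))
  }, numeric(1))
  partial <- character(0)
  if (!is.null(expected_runs)) {
    n_runs <- vapply(masks_by_subject, function(ms)
      if (is.logical(ms)) 1L else length(ms), integer(1))
    partial <- names(n_runs)[n_runs < expected_runs]
    if (length(partial))
      warning("subject(s) with missing runs, partial sums: ",
              paste(partial, collapse = ", "), call. = FALSE)
  }
  structure(as.integer(counts), names = names(masks_by_subject),
            partial = partial)
}

#' Normal-density summary of a group's post-censored counts
#'
#' @param counts Numeric vector of per-subject retained volume counts.
#' @param label Group label.
#' @return A `group_pdf`: label, mean, sd, and the density function.
#' @export
group_pdf <- function(counts, label = "group") {
  if (length(counts) < 2L) stop_invalid("need >= 2 subjects for a density")
  m <- mean(counts); s <- stats::sd(counts)
  if (s <= 0) stop_invalid("group '%s' has zero spread", label)
  structure(list(label = label, mean = m, sd = s,
                 density = function(x) stats::dnorm(x, m, s)),
            class = "group_pdf")
}

#' Intersection of two group density curves
#'
#' Under normal densities the equal-density condition is a quadratic in x;
#' the root lying between the two means is returned (with equal SDs this
#' is the midpoint of the means). That intersection is the natural cutoff
#' separating the two distributions of post-censored volume counts.
#'
#' @param group_a,group_b `group_pdf` objects with distinct means.
#' @param fallback_midpoint If no root lies between the means
#'   (pathological SDs), return the midpoint instead of erroring.
#' @return Threshold volume count (numeric).
#' @export
pdf_intersection <- function(group_a, group_b, fallback_midpoint = FALSE) {
  stopifnot(inherits(group_a, "group_pdf"), inherits(group_b, "group_pdf"))
  m1 <- group_a$mean; s1 <- group_a$sd
  m2 <- group_b$mean; s2 <- group_b$sd
  if (m1 == m2) stop_invalid("group means must differ")
  if (isTRUE(all.equal(s1, s2))) return((m1 + m2) / 2)
  # dnorm(x, m1, s1) = dnorm(x, m2, s2)  <=>  a x^2 + b x + c = 0
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log(s2 / s1)
  disc <- b^2 - 4 * a * cc
  lo <- min(m1, m2); hi <- max(m1, m2)
  roots <- if (disc >= 0)
    (-b + c(-1, 1) * sqrt(disc)) / (2 * a) else numeric(0)
  inside <- roots[roots > lo & roots < hi]
  if (!length(inside)) {
    if (fallback_midpoint) return((m1 + m2) / 2)
    stop_invalid(
      "no density intersection between the means (%g, %g); roots: %s",
      lo, hi, paste(signif(roots, 6), collapse = ", "))
  }
  inside[1L]
}

#' Classify subjects into motion groups
#'
#' Subjects whose post-censored volume count falls below the threshold
#' lose more data to censoring and are classified high-motion; counts at
#' or above the threshold are low-motion (ties go to low motion). The
#' final label crosses motion status with the subject's age group, giving
#' the four groups low/high-motion adult/child.
#'
#' @param counts Named numeric vector of post-censored volume counts.
#' @param threshold Volume-count threshold (e.g., from
#'   [pdf_intersection]).
#' @param age_labels Named character vector (`"adult"`/`"child"`) for the
#'   same subjects.
#' @return Data frame (subject_id, age_group, retained_volumes,
#'   motion, group) with a `threshold` attribute.
#' @export
classify_motion_groups <- function(counts, threshold, age_labels) {
  ids <- names(counts)
  if (is.null(ids) || !all(ids %in% names(age_labels)))
    stop_invalid("`counts` and `age_labels` must be named consistently")
  if (threshold < min(counts) || threshold > max(counts))
    warning("threshold lies outside the observed range of counts",
            call. = FALSE)
  motion <- ifelse(counts < threshold, "high_motion", "low_motion")
  grp <- paste(motion, unname(age_labels[ids]), sep = "_")
  structure(
    data.frame(subject_id = ids, age_group = unname(age_labels[ids]),
               retained_volumes = as.integer(counts),
               motion = unname(motion), group = unname(grp),
               row.names = NULL, stringsAsFactors = FALSE),
    threshold = threshold)
}

#' Exclude subjects with too little usable data
#'
#' Pre-classification filter: drops subjects whose post-censored data
#' falls below a minimum duration (default 40 minutes).
#'
#' @param counts Named post-censored volume counts.
#' @param min_minutes Minimum usable duration (minutes).
#' @param tr_seconds Repetition time (seconds).
#' @return The retained subset of `counts`, with attribute `excluded`.
#' @export
exclude_low_data <- function(counts, min_minutes = 40, tr_seconds = 2) {
  need <- minutes_to_volumes(min_minutes, tr_seconds)
  keep <- counts >= need
  structure(counts[keep], excluded = names(counts)[!keep])
}
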