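#' Session split schemes
#'
#' A split scheme is a list of pairs; each pair holds two disjoint session
#' sets that jointly cover all sessions. The default for four sessions is
#' the three balanced pairings: {1,4} vs {2,3}, {1,2} vs {3,4}, and
#' {1,3} vs {2,4}.
#'
#' @param n_sessions Number of sessions (the default scheme requires 4).
#' @param pairs Optional custom list of `list(a, b)` session-set pairs.
#' @return A `split_scheme` object.
#' @export
split_scheme <- function(n_sessions = 4, pairs = NULL) {
  if (is.null(pairs)) {
    if (n_sessions != 4)
      stop_invalid(
        "the default scheme is defined for 4 sessions; supply `pairs`")
    pairs <- list(list(a = c(1L, 4L), b = c(2L, 3L)),
                  list(a = c(1L, 2L), b = c(3L, 4L)),
                  list(a = c(1L, 3L), b = c(2L, 4L)))
  }
  all_sessions <- seq_len(n_sessions)
  for (p in pairs) {
    if (length(intersect(p$a, p$b)))
      stop_invalid("split halves must be disjoint")
    if (!setequal(c(p$a, p$b), all_sessions))
      stop_invalid("each split pair must cover all sessions")
  }
  structure(list(pairs = pairs, n_sessions = n_sessions),
            class = "split_scheme")
}

order_runs <- function(runs, acq = NULL) {
  conds <- if (!is.null(acq)) acq$conditions else
    sort(unique(vapply(runs, `[[`, character(1), "condition")))
  key <- vapply(runs, function(r)
    (match(r$condition, conds) - 1L) + length(conds) *
      ((r$session - 1L) * 1000L) + r$run / 100, numeric(1))
  runs[order(vapply(runs, `[[`, integer(1), "session"),
             vapply(runs, function(r) match(r$condition, conds), integer(1)),
             vapply(runs, `[[`, integer(1), "run"))]
}

reliability_curve <- function(grid_minutes, trc, subject_id, method,
                              condition_scope = "all", n_iterations = NA,
                              splits_used = NA) {
  structure(
    data.frame(duration_min = grid_minutes, trc = trc),
    subject_id = subject_id, method = method,
    condition_scope = condition_scope, n_iterations = n_iterations,
    splits_used = splits_used,
    class = c("reliability_curve", "data.frame"))
}

fc_edges_first_minutes <- function(data, minutes, tr_seconds) {
  need <- minutes_to_volumes(minutes, tr_seconds)
  if (ncol(data) < need || need < 3L) return(NULL)
  vectorize_upper(fisher_z(pearson_fc(data[, seq_len(need), drop = FALSE])))
}

#' Split-session test-retest correlation curve
#'
#' For each split pair the subject's censored runs are concatenated per
#' half in acquisition order (temporal sequencing preserved); at each grid
#' duration T the first T post-censored minutes of each half are turned
#' into Fisher-z connectomes and the two edge vectors Pearson-correlated.
#' Per-duration values are averaged across split pairs. Durations that any
#' half cannot supply are missing.
#'
#' @param runs One subject's `parcellated_ts` runs (all sessions).
#' @param masks Censor masks parallel to `runs` (default: FD censoring at
#'   0.15 mm).
#' @param scheme A [split_scheme].
#' @param grid_minutes Strictly increasing post-censored durations
#'   (minutes); default 5 to 80 by 5.
#' @param acq Optional [acquisition_spec] fixing condition order for the
#'   concatenation.
#' @return A `reliability_curve` data frame (`duration_min`, `trc`).
#' @export
split_session_trc <- function(runs,
                              masks = lapply(runs, function(r) censor(r$fd)),
                              scheme = split_scheme(),
                              grid_minutes = seq(5, 80, by = 5),
                              acq = NULL) {
  stopifnot(length(runs) >= 2L, length(runs) == length(masks))
  check_duration_grid(grid_minutes)
  tr <- runs[[1L]]$tr_seconds
  sessions <- vapply(runs, `[[`, integer(1), "session")

  half_data <- function(session_set) {
    sel <- which(sessions %in% session_set)
    if (!length(sel)) return(NULL)
    sel_runs <- order_runs(runs[sel], acq)
    sel_masks <- masks[sel][match_run_ids(sel_runs, runs[sel])]
    concat_censored(sel_runs, sel_masks)
  }

  per_split <- matrix(NA_real_, length(scheme$pairs), length(grid_minutes))
  for (pi in seq_along(scheme$pairs)) {
    p <- scheme$pairs[[pi]]
    da <- half_data(p$a)
    db <- half_data(p$b)
    if (is.null(da) || is.null(db)) next
    for (gi in seq_along(grid_minutes)) {
      ea <- fc_edges_first_minutes(da, grid_minutes[gi], tr)
      eb <- fc_edges_first_minutes(db, grid_minutes[gi], tr)
      if (is.null(ea) || is.null(eb)) next
      per_split[pi, gi] <- stats::cor(ea, eb)
    }
  }
  trc <- colMeans(per_split, na.rm = TRUE)
  trc[is.nan(trc)] <- NA_real_
  # a duration is reported only when every split could supply it
  trc[colSums(is.na(per_split)) > 0] <- NA_real_
  reliability_curve(grid_minutes, trc, runs[[1L]]$subject_id,
                    "split_session",
                    splits_used = length(scheme$pairs))
}

match_run_ids <- function(ordered, original) {
  key <- function(r) paste(r$subject_id, r$session, r$condition, r$run)
  match(vapply(ordered, key, character(1)),
        vapply(original, key, character(1)))
}

check_duration_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1L || any(grid <= 0) ||
      is.unsorted(grid, strictly = TRUE))
    stop_invalid("duration grid must be strictly increasing and positive")
}

#' Iterative (reference vs residual) test-retest correlation curve
#'
#' Censored data from all runs are concatenated and tiled into fixed
#' 1-minute chunks (the final partial chunk is dropped). Each iteration
#' samples chunks without replacement to build a "true" reference
#' connectome (default 60 post-censored minutes) and, for every grid
#' duration T, samples T minutes of chunks from the residual (temporal
#' order not preserved); the TRC is the Pearson correlation of the two
#' Fisher-z edge vectors, averaged over iterations.
#'
#' @param runs One subject's runs, or a premade node x volume matrix.
#' @param masks Censor masks (ignored when `runs` is already a matrix).
#' @param reference_minutes Reference subset size, minutes.
#' @param chunk_minutes Chunk length, minutes.
#' @param grid_minutes Residual-subset durations (minutes).
#' @param n_iterations Monte-Carlo iterations.
#' @param seed Integer seed; curves are reproducible.
#' @param tr_seconds TR; taken from the runs when available.
#' @return A `reliability_curve`; durations the residual cannot supply are
#'   missing. If the reference itself is infeasible the whole curve is
#'   missing with attribute `infeasible = TRUE`.
#' @export
iterative_trc <- function(runs, masks = NULL, reference_minutes = 60,
                          chunk_minutes = 1,
                          grid_minutes = seq(5, 80, by = 5),
                          n_iterations = 1000, seed = 1,
                          tr_seconds = NULL) {
  check_duration_grid(grid_minutes)
  if (is.matrix(runs)) {
    data <- runs
    if (is.null(tr_seconds))
      stop_invalid("`tr_seconds` is required with matrix input")
    subject_id <- "matrix-input"
  } else {
    if (is.null(masks)) masks <- lapply(runs, function(r) censor(r$fd))
    data <- concat_censored(order_runs(runs), masks[
      match_run_ids(order_runs(runs), runs)])
    tr_seconds <- runs[[1L]]$tr_seconds
    subject_id <- runs[[1L]]$subject_id
  }
  chunk_vols <- minutes_to_volumes(chunk_minutes, tr_seconds)
  n_chunks <- floor(ncol(data) / chunk_vols)
  ref_chunks <- ceiling(reference_minutes / chunk_minutes)
  grid_chunks <- ceiling(grid_minutes / chunk_minutes)

  if (n_chunks < ref_chunks + min(grid_chunks)) {
    curve <- reliability_curve(grid_minutes, rep(NA_real_,
                                                 length(grid_minutes)),
                               subject_id, "iterative",
                               n_iterations = n_iterations)
    attr(curve, "infeasible") <- TRUE
    return(curve)
  }
  chunk_cols <- lapply(seq_len(n_chunks), function(k)
    ((k - 1L) * chunk_vols + 1L):(k * chunk_vols))

  acc <- matrix(NA_real_, n_iterations, length(grid_minutes))
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      ref_ids <- sample(n_chunks, ref_chunks)
      residual_ids <- setdiff(seq_len(n_chunks), ref_ids)
      ref_cols <- unlist(chunk_cols[ref_ids])
      e_ref <- vectorize_upper(fisher_z(pearson_fc(
        data[, ref_cols, drop = FALSE])))
      for (gi in seq_along(grid_chunks)) {
        k <- grid_chunks[gi]
        if (length(residual_ids) < k) next
        pick <- sample(residual_ids, k)
        e_res <- vectorize_upper(fisher_z(pearson_fc(
          data[, unlist(chunk_cols[pick]), drop = FALSE])))
        acc[it, gi] <- stats::cor(e_ref, e_res)
      }
    }
  })
  trc <- colMeans(acc)
  trc[is.nan(trc)] <- NA_real_
  reliability_curve(grid_minutes, trc, subject_id, "iterative",
                    n_iterations = n_iterations)
}

#' Scan time required to reach a reliability threshold
#'
#' Returns the smallest duration at which the curve reaches the threshold,
#' linearly interpolating between the bracketing grid points when the
#' crossing falls off-grid. If the first non-missing point already meets
#' the threshold, that duration is returned.
#'
#' @param curve A `reliability_curve` (or data frame with `duration_min`
#'   and `trc`).
#' @param threshold Reliability threshold (default 0.8).
#' @return Minutes, or `NA` with attribute `reason = "unreachable"`.
#' @export
time_to_threshold <- function(curve, threshold = 0.8) {
  ok <- !is.na(curve$trc)
  if (!any(ok)) return(structure(NA_real_, reason = "unreachable"))
  t <- curve$duration_min[ok]
  v <- curve$trc[ok]
  hit <- which(v >= threshold)
  if (!length(hit)) return(structure(NA_real_, reason = "unreachable"))
  h <- hit[1L]
  if (h == 1L) return(t[1L])
  t[h - 1L] + (threshold - v[h - 1L]) / (v[h] - v[h - 1L]) *
    (t[h] - t[h - 1L])
}

#' Cohen's d between two groups of values
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled SD using (n - 1)
#' weights.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return d, or `NA` when the pooled SD is zero.
#' @export
cohens_d <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop_invalid("each group needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Incremental reliability benefit of additional scan time
#'
#' First differences of the curve along its grid, aligned to the later
#' duration of each step.
#'
#' @param curve A `reliability_curve`.
#' @return Data frame `duration_min` (the later duration), `delta_trc`.
#' @export
incremental_benefit <- function(curve) {
  ok <- which(!is.na(curve$trc))
  if (length(ok) < 2L) stop_invalid("need >= 2 non-missing curve points")
  d <- diff(curve$trc[ok])
  data.frame(duration_min = curve$duration_min[ok][-1L], delta_trc = d)
}

#' Condition-wise split-session reliability curve
#'
#' [split_session_trc] restricted to the runs of one viewing condition,
#' on a finer grid (default 1 to 22 minutes in 1-minute steps).
#'
#' @inheritParams split_session_trc
#' @param condition Condition name to keep.
#' @export
condition_trc <- function(runs, masks = lapply(runs,
                                               function(r) censor(r$fd)),
                          condition, scheme = split_scheme(),
                          grid_minutes = 1:22, acq = NULL) {
  keep <- vapply(runs, function(r) r$condition == condition, logical(1))
  if (!any(keep)) stop_invalid("no runs of condition '%s'", condition)
  curve <- split_session_trc(runs[keep], masks[keep], scheme,
                             grid_minutes, acq)
  attr(curve, "condition_scope") <- condition
  curve
}

#' Group-level reliability curve summary
#'
#' Stacks per-subject curves and summarizes per duration: group means, the
#' effect size between two named groups, and mean incremental benefit.
#'
#' @param curves Named list of `reliability_curve`s (names are subject
#'   ids).
#' @param groups Named character vector mapping subject id to group.
#' @param d_pair Length-2 character vector of group names compared by
#'   Cohen's d (first minus second), or `NULL` to skip.
#' @return Data frame (group, duration_min, mean_trc, n, cohens_d).
#' @export
summarize_trc <- function(curves, groups, d_pair = NULL) {
  long <- do.call(rbind, lapply(names(curves), function(id) {
    cbind(subject_id = id, as.data.frame(curves[[id]]))
  }))
  long$group <- unname(groups[long$subject_id])
  agg <- stats::aggregate(trc ~ group + duration_min, long,
                          function(x) c(mean = mean(x, na.rm = TRUE),
                                        n = sum(!is.na(x))),
                          na.action = stats::na.pass)
  out <- data.frame(group = agg$group, duration_min = agg$duration_min,
                    mean_trc = agg$trc[, "mean"], n = agg$trc[, "n"])
  if (!is.null(d_pair)) {
    ds <- vapply(sort(unique(long$duration_min)), function(t) {
      a <- long$trc[long$duration_min == t & long$group == d_pair[1L]]
      b <- long$trc[long$duration_min == t & long$group == d_pair[2L]]
      if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) return(NA_real_)
      cohens_d(a, b)
    }, numeric(1))
    out$cohens_d <- ds[match(out$duration_min,
                             sort(unique(long$duration_min)))]
  }
  out[order(out$group, out$duration_min), ]
}
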