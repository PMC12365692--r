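#' Pipeline configuration
#'
#' Collects every constant the end-to-end analysis needs. The defaults
#' are the study-scale settings (FD threshold 0.15 mm, TRC threshold 0.8,
#' 5-80 minute grid in 5-minute steps, ICC split-half durations
#' 5/10/24/54 minutes, consensus thresholds 66% and 75%);
#' [demo_pipeline_config] scales the cohort down for quick end-to-end
#' runs.
#'
#' @param acq An [acquisition_spec].
#' @param cohort A [cohort_config] (its seed is re-derived from `seed`).
#' @param fd_threshold_mm Censoring threshold (mm).
#' @param trc_threshold Reliability threshold for time-to-threshold.
#' @param grid_minutes Split-session duration grid (minutes).
#' @param icc_durations Split-half durations for the ICC sweep (minutes).
#' @param consensus_thresholds Group-overlap thresholds (fractions).
#' @param iterative_iterations Iterations for the iterative TRC stage
#'   (0 skips the stage).
#' @param iterative_reference_minutes Reference-subset size (minutes).
#' @param d_pair Groups compared by Cohen's d in the TRC summary.
#' @param min_usable_minutes Exclusion cutoff on post-censored data.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(acq = acquisition_spec(),
                            cohort = cohort_config(),
                            fd_threshold_mm = 0.15,
                            trc_threshold = 0.8,
                            grid_minutes = seq(5, 80, by = 5),
                            icc_durations = c(5, 10, 24, 54),
                            consensus_thresholds = c(0.66, 0.75),
                            iterative_iterations = 0,
                            iterative_reference_minutes = 60,
                            d_pair = c("low_motion_adult",
                                       "high_motion_child"),
                            min_usable_minutes = 40,
                            seed = 1L,
                            out_dir = NULL) {
  check_scalar_positive(fd_threshold_mm, "fd_threshold_mm")
  stopifnot(trc_threshold > 0, trc_threshold <= 1,
            all(consensus_thresholds > 0 & consensus_thresholds <= 1))
  check_duration_grid(grid_minutes)
  check_duration_grid(icc_durations)
  cohort$seed <- derive_seed(seed, 11)
  structure(
    list(acq = acq, cohort = cohort, fd_threshold_mm = fd_threshold_mm,
         trc_threshold = trc_threshold, grid_minutes = grid_minutes,
         icc_durations = icc_durations,
         consensus_thresholds = consensus_thresholds,
         iterative_iterations = iterative_iterations,
         iterative_reference_minutes = iterative_reference_minutes,
         d_pair = d_pair, min_usable_minutes = min_usable_minutes,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param ... Overrides forwarded to [pipeline_config].
#' @export
demo_pipeline_config <- function(seed = 1L, out_dir = NULL, ...) {
  acq <- acquisition_spec(volumes_per_run = 75, n_sessions = 4)
  cohort <- cohort_config(
    n_nodes = 40,
    network_labels = default_network_labels(
      40, c("DMN", "FP", "visual", "DAN", "SAL", "AUD", "CON", "SMd")),
    n_pairs = 4, subject_deviation_scale = 0.1,
    observation_noise_scale = 1,
    high_motion_child_frac = 0.5)
  pipeline_config(acq = acq, cohort = cohort,
                  grid_minutes = seq(2, 14, by = 2),
                  icc_durations = c(2, 5, 10),
                  iterative_iterations = 10,
                  iterative_reference_minutes = 10,
                  min_usable_minutes = 5,
                  seed = seed, out_dir = out_dir, ...)
}

config_hash <- function(config) {
  plain <- unclass(config)
  plain$out_dir <- NULL   # hash the scientific settings, not the paths
  plain <- rapply(plain, function(x)
    if (is.function(x)) NULL else x, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_stage_csv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> censor -> group -> reliability curves ->
#' time-to-threshold -> ICC sweep -> template matching/consensus ->
#' behavior scoring, writing per-stage CSVs and a JSON report (when
#' `config$out_dir` is set). Reruns with an identical configuration and
#' seed reproduce identical outputs; the report carries the
#' configuration's MD5 hash for provenance.
#'
#' @param config A [pipeline_config].
#' @param quiet Suppress per-stage progress messages.
#' @return The run report (list), invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  report <- list(config_hash = hash, seed = config$seed, stages = list(),
                 warnings = list())
  note <- function(stage, w) {
    report$warnings[[stage]] <<- c(report$warnings[[stage]], w)
  }

  say("[simulate] generating cohort (seed %d)", config$cohort$seed)
  cohort <- generate_cohort(config$cohort, config$acq)
  report$stages$simulate <- list(
    n_runs = length(cohort$runs),
    n_subjects = length(cohort$registry),
    n_nodes = config$cohort$n_nodes)

  say("[censor] FD threshold %.3g mm", config$fd_threshold_mm)
  masks <- lapply(cohort$runs, function(r)
    censor(r$fd, config$fd_threshold_mm))
  retention <- retention_summary(cohort$runs, masks, config$acq)
  write_stage_csv(retention, out_dir, "retention.csv")
  report$stages$censor <- list(
    mean_retention_percent = mean(retention$percent),
    min_retention_percent = min(retention$percent))

  subj_ids <- vapply(cohort$runs, `[[`, character(1), "subject_id")
  runs_by_subject <- split(cohort$runs, subj_ids)
  masks_by_subject <- split(masks, subj_ids)
  age <- vapply(cohort$registry, `[[`, character(1), "age_group")

  say("[group] classifying motion groups")
  counts <- postcensored_counts(masks_by_subject)
  usable <- withCallingHandlers(
    exclude_low_data(counts, config$min_usable_minutes,
                     config$acq$tr_seconds),
    warning = function(w) {
      note("group", conditionMessage(w)); invokeRestart("muffleWarning")
    })
  threshold <- tryCatch({
    pdfs <- lapply(c(adult = "adult", child = "child"), function(g) {
      ids <- intersect(names(usable), names(age)[age == g])
      group_pdf(usable[ids], g)
    })
    pdf_intersection(pdfs$adult, pdfs$child, fallback_midpoint = TRUE)
  }, error = function(e) {
    # degenerate distributions (tiny cohorts): midpoint of the group means
    note("group", conditionMessage(e))
    gm <- vapply(c("adult", "child"), function(g)
      mean(usable[intersect(names(usable), names(age)[age == g])]),
      numeric(1))
    mean(gm, na.rm = TRUE)
  })
  groups_df <- withCallingHandlers(
    classify_motion_groups(usable, threshold, age),
    warning = function(w) {
      note("group", conditionMessage(w)); invokeRestart("muffleWarning")
    })
  write_stage_csv(groups_df, out_dir, "motion_groups.csv")
  groups <- stats::setNames(groups_df$group, groups_df$subject_id)
  report$stages$group <- list(
    threshold_volumes = threshold,
    sizes = as.list(table(groups_df$group)),
    excluded = attr(usable, "excluded"))

  say("[trc] split-session curves, grid %s min",
      paste(range(config$grid_minutes), collapse = "-"))
  scheme <- split_scheme(config$acq$n_sessions)
  curves <- lapply(names(groups), function(id) {
    split_session_trc(runs_by_subject[[id]], masks_by_subject[[id]],
                      scheme, config$grid_minutes, config$acq)
  })
  names(curves) <- names(groups)
  long <- do.call(rbind, lapply(names(curves), function(id)
    data.frame(subject_id = id, method = "split_session",
               as.data.frame(curves[[id]]))))
  d_pair <- if (all(config$d_pair %in% groups)) config$d_pair else NULL
  trc_summary <- summarize_trc(curves, groups, d_pair)
  ttt <- data.frame(
    subject_id = names(curves),
    group = unname(groups[names(curves)]),
    mean_fd = vapply(names(curves), function(id)
      mean(unlist(lapply(runs_by_subject[[id]], `[[`, "fd"))), numeric(1)),
    time_to_threshold_min = vapply(curves, function(cv)
      as.numeric(time_to_threshold(cv, config$trc_threshold)), numeric(1)),
    row.names = NULL)
  if (config$iterative_iterations > 0) {
    say("[trc] iterative curves (%d iterations)",
        config$iterative_iterations)
    it_curves <- lapply(names(groups), function(id) {
      iterative_trc(runs_by_subject[[id]], masks_by_subject[[id]],
                    reference_minutes = config$iterative_reference_minutes,
                    grid_minutes = config$grid_minutes,
                    n_iterations = config$iterative_iterations,
                    seed = derive_seed(config$seed, 21,
                                       match(id, names(groups))))
    })
    names(it_curves) <- names(groups)
    long <- rbind(long, do.call(rbind, lapply(names(it_curves),
      function(id) data.frame(subject_id = id, method = "iterative",
                              as.data.frame(it_curves[[id]])))))
  }
  write_stage_csv(long, out_dir, "trc_curves.csv")
  write_stage_csv(trc_summary, out_dir, "trc_summary.csv")
  write_stage_csv(ttt, out_dir, "time_to_threshold.csv")
  report$stages$trc <- list(
    mean_time_to_threshold = lapply(
      split(ttt$time_to_threshold_min, ttt$group),
      function(x) mean(x, na.rm = TRUE)),
    unreachable = sum(is.na(ttt$time_to_threshold_min)))

  say("[icc] network ICC sweep")
  icc_sweep <- withCallingHandlers(
    network_icc_by_duration(runs_by_subject, groups,
                            config$cohort$network_labels,
                            durations = config$icc_durations,
                            masks_by_subject = masks_by_subject),
    warning = function(w) {
      note("icc", conditionMessage(w)); invokeRestart("muffleWarning")
    })
  write_stage_csv(icc_sweep, out_dir, "network_icc_by_duration.csv")
  report$stages$icc <- list(
    rows = nrow(icc_sweep),
    mean_icc_by_group = lapply(split(icc_sweep$mean_icc, icc_sweep$group),
                               mean))

  say("[networks] template matching + consensus maps")
  template <- network_template(config$cohort$network_labels)
  assignments <- lapply(names(groups), function(id) {
    data <- concat_censored(runs_by_subject[[id]], masks_by_subject[[id]])
    withCallingHandlers(
      template_match(fisher_z(pearson_fc(data)), template),
      warning = function(w) {
        note("networks", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  consensus <- lapply(config$consensus_thresholds, function(thr)
    group_overlap(assignments, thr))
  names(consensus) <- sprintf("consensus_%02d",
                              round(100 * config$consensus_thresholds))
  for (nm in names(consensus))
    write_stage_csv(consensus[[nm]], out_dir, paste0(nm, ".csv"))
  report$stages$networks <- lapply(consensus, function(cs)
    list(labeled = sum(!is.na(cs$network))))

  say("[behavior] scoring surveys")
  report$stages$behavior <- tryCatch({
    behavior <- score_surveys(cohort$surveys)
    write_stage_csv(behavior, out_dir, "behavior_scores.csv")
    list(
      mean_attention = lapply(split(behavior$attention,
                                    behavior$condition), mean),
      mean_drowsiness = lapply(split(behavior$drowsiness,
                                     behavior$condition), mean))
  }, error = function(e) {
    note("behavior", conditionMessage(e))
    list(skipped = TRUE)
  })

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("[report] written to %s", file.path(out_dir, "report.json"))
    return(invisible(report))
  }
  report
}
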