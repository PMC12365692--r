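#' Two-state head-motion model
#'
#' Per-volume framewise displacement is modeled as a constant baseline
#' "floor" plus, with probability `burst_prob`, a lognormal burst. Burst
#' magnitudes can fall below the censoring threshold, so some contaminated
#' volumes survive censoring — censoring then has a measurable (but not
#' total) benefit, as in real data.
#'
#' @param baseline_fd Constant baseline FD level (mm); the per-subject
#'   "floor" seen in low-motion scans.
#' @param burst_prob Probability that any volume carries a motion burst;
#'   either a scalar or a length-2 range `c(lo, hi)` from which each
#'   subject's rate is drawn uniformly (see [realize_motion_model]).
#' @param burst_meanlog,burst_sdlog Lognormal parameters of burst
#'   magnitude (mm, added to baseline). The default centers bursts near a
#'   0.15 mm censoring threshold so that a realistic share of spikes
#'   survives censoring.
#' @return A `motion_model` object.
#' @export
motion_model <- function(baseline_fd = 0.05, burst_prob = 0.02,
                         burst_meanlog = log(0.15), burst_sdlog = 1) {
  check_scalar_nonneg(baseline_fd, "baseline_fd")
  if (!length(burst_prob) %in% 1:2 || any(burst_prob < 0) ||
      any(burst_prob > 1) || is.unsorted(burst_prob))
    stop_invalid("`burst_prob` must be a probability or a sorted range")
  structure(list(baseline_fd = baseline_fd, burst_prob = burst_prob,
                 burst_meanlog = burst_meanlog, burst_sdlog = burst_sdlog),
            class = "motion_model")
}

#' Draw a subject-level motion model from a group-level one
#'
#' When the group model carries a burst-probability range, each subject's
#' rate is drawn uniformly from it (motion heterogeneity within a group);
#' a scalar model is returned unchanged.
#'
#' @param model A [motion_model].
#' @param seed Integer seed.
#' @return A [motion_model] with scalar `burst_prob`.
#' @export
realize_motion_model <- function(model, seed) {
  stopifnot(inherits(model, "motion_model"))
  if (length(model$burst_prob) == 1L) return(model)
  p <- with_seed(seed, stats::runif(1, model$burst_prob[1L],
                                    model$burst_prob[2L]))
  motion_model(model$baseline_fd, p, model$burst_meanlog, model$burst_sdlog)
}

#' Analytic probability that a volume exceeds the censoring threshold
#'
#' Under the two-state model, `P(FD > thr) = p_burst * P(baseline + M > thr)`
#' when the baseline is below the threshold (M lognormal), and 1 otherwise.
#'
#' @param model A [motion_model].
#' @param threshold_mm Censoring threshold (mm).
#' @export
burst_exceedance_prob <- function(model, threshold_mm = 0.15) {
  stopifnot(inherits(model, "motion_model"),
            length(model$burst_prob) == 1L)
  if (model$baseline_fd > threshold_mm) return(1)
  excess <- threshold_mm - model$baseline_fd
  model$burst_prob *
    stats::plnorm(excess, model$burst_meanlog, model$burst_sdlog,
                  lower.tail = FALSE)
}

#' Block-structured group correlation template
#'
#' Builds a node x node correlation matrix with elevated correlation within
#' each functional network and a common background between networks — the
#' canonical community structure of resting/viewing FC.
#'
#' @param network_labels Character (or factor) vector assigning each node
#'   to a network.
#' @param within_r Correlation between nodes of the same network.
#' @param between_r Correlation between nodes of different networks.
#' @return Correlation matrix with unit diagonal.
#' @export
block_template <- function(network_labels, within_r = 0.35, between_r = 0) {
  labels <- as.character(network_labels)
  n <- length(labels)
  same <- outer(labels, labels, `==`)
  m <- matrix(between_r, n, n)
  m[same] <- within_r
  diag(m) <- 1
  check_correlation_matrix(m, "block template")
  m
}

#' Evenly spread network labels over a node set
#'
#' @param n_nodes Number of nodes.
#' @param networks Network names to cycle over (default: 14 canonical
#'   functional networks).
#' @return Character vector of length `n_nodes`, grouped by network.
#' @export
default_network_labels <- function(n_nodes,
                                   networks = c("DMN", "FP", "visual", "DAN",
                                                "VAN", "SAL", "AUD", "CON",
                                                "SMd", "SMl", "Tpole", "MTL",
                                                "PMN", "PON")) {
  sort(rep_len(networks, n_nodes))
}

#' Draw a subject-specific latent connectome around a group template
#'
#' Adds symmetric Gaussian noise to the Fisher-z transform of the
#' template's off-diagonal entries, transforms back, and projects to the
#' nearest correlation matrix so the result is a valid (PSD, unit-diagonal)
#' correlation matrix. `deviation_scale = 0` returns the template exactly.
#'
#' @param template Group-level correlation matrix (symmetric, unit
#'   diagonal, PSD).
#' @param deviation_scale SD of the Fisher-z perturbation (nonnegative).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A correlation matrix of the same dimension.
#' @export
generate_latent_connectome <- function(template, deviation_scale, seed) {
  check_correlation_matrix(template, "template")
  check_scalar_nonneg(deviation_scale, "deviation_scale")
  if (deviation_scale == 0) return(template)
  n <- nrow(template)
  with_seed(seed, {
    z <- atanh(pmin(pmax(template, -1 + 1e-7), 1 - 1e-7))
    noise <- matrix(stats::rnorm(n * n, sd = deviation_scale), n, n)
    noise <- (noise + t(noise)) / sqrt(2)   # symmetric, per-entry SD preserved
    z <- z + noise
    m <- tanh(z)
    diag(m) <- 1
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      m <- as.matrix(Matrix::nearPD(m, corr = TRUE, maxit = 200)$mat)
      m <- (m + t(m)) / 2
      diag(m) <- 1
    }
    m
  })
}

#' Simulate one parcellated BOLD run with its FD trace
#'
#' Draws a node x volume signal matrix from a multivariate normal whose
#' correlation structure is the subject's latent connectome (scaled by the
#' condition's temporal-SD multiplier), plus independent observation noise,
#' plus an optional rank-one motion artifact whose amplitude scales with
#' the volume's framewise displacement. The FD trace comes from the
#' two-state [motion_model]; burst indicators are drawn from a per-volume
#' uniform stream, so under a common seed the burst set at probability p is
#' nested within the burst set at any larger probability.
#'
#' @param latent Subject latent connectome (correlation matrix).
#' @param acq An [acquisition_spec] (supplies TR and volumes per run).
#' @param noise_scale SD of i.i.d. observation noise added per node/volume
#'   (signal scale is 1 before the SD multiplier).
#' @param sd_multiplier Condition-specific temporal-SD multiplier.
#' @param motion A [motion_model].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param subject_id,session,condition,run Identifiers carried on the run.
#' @param contamination_scale Amplitude of the rank-one artifact added
#'   during motion spikes; the artifact scales with the FD excess above
#'   the baseline floor, so only burst volumes are contaminated (0
#'   disables it).
#' @param latent_factor Optional precomputed symmetric square root of
#'   `latent` (an optimization for repeated runs of one subject; must
#'   satisfy `latent_factor %*% t(latent_factor) = latent`).
#' @return A `parcellated_ts`: list with `signal` (node x volume matrix),
#'   `fd`, identifiers, `node_ids`, and `tr_seconds`.
#' @export
generate_run <- function(latent, acq, noise_scale = 1, sd_multiplier = 1,
                         motion = motion_model(), seed = 1,
                         subject_id = "sub-01", session = 1L,
                         condition = acq$conditions[1L], run = 1L,
                         contamination_scale = 0, latent_factor = NULL) {
  check_correlation_matrix(latent, "latent")
  stopifnot(inherits(acq, "acquisition_spec"), inherits(motion, "motion_model"))
  if (length(motion$burst_prob) != 1L)
    stop_invalid("run generation needs a subject-level (scalar) ",
                 "burst probability; see realize_motion_model()")
  check_scalar_nonneg(noise_scale, "noise_scale")
  check_scalar_positive(sd_multiplier, "sd_multiplier")
  n <- nrow(latent)
  v <- acq$volumes_per_run
  with_seed(seed, {
    # motion stream first, fixed draw order for cross-probability coupling
    u <- stats::runif(v)
    mag <- stats::rlnorm(v, motion$burst_meanlog, motion$burst_sdlog)
    fd <- rep(motion$baseline_fd, v)
    burst <- u < motion$burst_prob
    fd[burst] <- fd[burst] + mag[burst]
    fd[1L] <- 0

    l <- if (is.null(latent_factor)) corr_sqrt(latent) else latent_factor
    x <- sd_multiplier * (l %*% matrix(stats::rnorm(n * v), n, v))
    if (noise_scale > 0)
      x <- x + noise_scale * matrix(stats::rnorm(n * v), n, v)
    if (contamination_scale > 0) {
      w <- stats::rnorm(n)
      spike <- pmax(fd - motion$baseline_fd, 0)
      x <- x + contamination_scale * (w %o% spike)
    }
    structure(
      list(subject_id = subject_id, session = as.integer(session),
           condition = condition, run = as.integer(run),
           signal = x, node_ids = sprintf("node%03d", seq_len(n)),
           tr_seconds = acq$tr_seconds, fd = fd),
      class = "parcellated_ts")
  })
}

# Symmetric PSD square root of a correlation matrix.
corr_sqrt <- function(m) {
  ev <- eigen(m, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  ev$vectors %*% (sqrt(lam) * t(ev$vectors))
}

#' Configure a synthetic multi-session cohort
#'
#' Defaults emulate a parent-child precision-fMRI sample: 24 pairs scanned
#' in 4 sessions of 3 viewing conditions x 2 runs x 205 volumes (TR 2 s),
#' adults with uniformly low motion and children split into lower- and
#' higher-motion subsets.
#'
#' @param n_nodes Number of parcels.
#' @param network_labels Node-to-network map (length `n_nodes`).
#' @param n_pairs Number of parent-child pairs.
#' @param group_fc_templates Named list (`adult`, `child`) of group latent
#'   correlation templates.
#' @param subject_deviation_scale Fisher-z SD of subject deviation from the
#'   group template; scalar or named per-group.
#' @param observation_noise_scale Per-volume i.i.d. noise SD.
#' @param motion_models List with entries `adult` (a [motion_model]) and
#'   `child` (list of `low` and `high` [motion_model]s).
#' @param high_motion_child_frac Fraction of children assigned the
#'   high-motion model (default 14/24).
#' @param condition_sd_multipliers Named per-condition temporal-SD
#'   multipliers.
#' @param condition_burst_multipliers Named per-condition multipliers on
#'   burst probability (engaging conditions can lower it).
#' @param contamination_scale FD-scaled artifact amplitude (see
#'   [generate_run]).
#' @param session_zshift_scale SD of a session-specific Fisher-z offset
#'   applied to the latent connectome (day-to-day state variance; 0
#'   disables it).
#' @param seed Master seed for the whole cohort.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_nodes = 100,
                          network_labels = default_network_labels(n_nodes),
                          n_pairs = 24,
                          group_fc_templates = NULL,
                          subject_deviation_scale = 0.1,
                          observation_noise_scale = 0.5,
                          motion_models = list(
                            adult = motion_model(0.05, c(0.005, 0.05)),
                            child = list(
                              low = motion_model(0.06, c(0.02, 0.10)),
                              high = motion_model(0.08, c(0.15, 0.45)))),
                          high_motion_child_frac = 14 / 24,
                          condition_sd_multipliers = NULL,
                          condition_burst_multipliers = NULL,
                          contamination_scale = 15,
                          session_zshift_scale = 0,
                          seed = 1L) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  n_pairs <- check_count(n_pairs, "n_pairs")
  stopifnot(length(network_labels) == n_nodes)
  if (is.null(group_fc_templates)) {
    tmpl <- block_template(network_labels)
    group_fc_templates <- list(adult = tmpl, child = tmpl)
  }
  for (g in names(group_fc_templates))
    check_correlation_matrix(group_fc_templates[[g]],
                             sprintf("group template '%s'", g))
  structure(
    list(n_nodes = n_nodes, network_labels = as.character(network_labels),
         n_pairs = n_pairs, group_fc_templates = group_fc_templates,
         subject_deviation_scale = subject_deviation_scale,
         observation_noise_scale = observation_noise_scale,
         motion_models = motion_models,
         high_motion_child_frac = high_motion_child_frac,
         condition_sd_multipliers = condition_sd_multipliers,
         condition_burst_multipliers = condition_burst_multipliers,
         contamination_scale = contamination_scale,
         session_zshift_scale = session_zshift_scale,
         seed = as.integer(seed)),
    class = "cohort_config")
}

group_deviation_scale <- function(config, group) {
  s <- config$subject_deviation_scale
  if (length(s) > 1L || !is.null(names(s))) {
    if (!group %in% names(s))
      stop_invalid("no subject_deviation_scale for group '%s'", group)
    return(unname(s[[group]]))
  }
  s
}

scaled_motion_model <- function(model, burst_multiplier) {
  if (is.null(burst_multiplier) || burst_multiplier == 1) return(model)
  motion_model(model$baseline_fd,
               min(1, model$burst_prob * burst_multiplier),
               model$burst_meanlog, model$burst_sdlog)
}

#' Generate a full synthetic cohort
#'
#' Emits every run of the configured design (pairs x 2 subjects x sessions
#' x conditions x runs) together with a ground-truth registry holding each
#' subject's latent connectome, age group, and motion parameters, and a
#' synthetic post-session survey table. Identical `config` (including its
#' seed) reproduces the cohort bit for bit.
#'
#' @param config A [cohort_config].
#' @param acq An [acquisition_spec].
#' @param out_dir Optional directory; when given, runs, confounds,
#'   ground-truth matrices, and a JSON manifest are written there as
#'   delimited text (see [write_cohort]).
#' @return A `synthetic_cohort`: list with `runs` (list of
#'   `parcellated_ts`), `registry` (per-subject truth), `surveys`
#'   (data.frame), `config`, and `acq`.
#' @export
generate_cohort <- function(config, acq = acquisition_spec(),
                            out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(acq, "acquisition_spec"))
  n_children <- config$n_pairs
  n_high <- round(config$high_motion_child_frac * n_children)
  child_motion_kind <- with_seed(
    derive_seed(config$seed, 7001),
    sample(rep(c("high", "low"),
               c(n_high, n_children - n_high))))

  subjects <- list()
  for (i in seq_len(config$n_pairs)) {
    subjects[[length(subjects) + 1L]] <-
      list(subject_id = sprintf("sub-A%02d", i), age_group = "adult",
           pair = i,
           motion = realize_motion_model(
             config$motion_models$adult,
             derive_seed(config$seed, 5000, i, 1)))
    mm <- config$motion_models$child[[child_motion_kind[i]]]
    subjects[[length(subjects) + 1L]] <-
      list(subject_id = sprintf("sub-C%02d", i), age_group = "child",
           pair = i,
           motion = realize_motion_model(
             mm, derive_seed(config$seed, 5000, i, 2)),
           motion_kind = child_motion_kind[i])
  }

  sd_mult <- config$condition_sd_multipliers
  if (is.null(sd_mult))
    sd_mult <- stats::setNames(rep(1, length(acq$conditions)),
                               acq$conditions)
  burst_mult <- config$condition_burst_multipliers
  if (is.null(burst_mult))
    burst_mult <- stats::setNames(rep(1, length(acq$conditions)),
                                  acq$conditions)

  runs <- list()
  registry <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    template <- config$group_fc_templates[[sub$age_group]]
    latent <- generate_latent_connectome(
      template, group_deviation_scale(config, sub$age_group),
      seed = derive_seed(config$seed, 1000, si))
    registry[[sub$subject_id]] <-
      list(subject_id = sub$subject_id, age_group = sub$age_group,
           pair = sub$pair, latent = latent, motion = sub$motion)
    for (ses in seq_len(acq$n_sessions)) {
      latent_ses <- session_latent(latent, config$session_zshift_scale,
                                   derive_seed(config$seed, 2000, si, ses))
      latent_factor <- corr_sqrt(latent_ses)
      for (ci in seq_along(acq$conditions)) {
        cond <- acq$conditions[ci]
        mm <- scaled_motion_model(sub$motion, burst_mult[[cond]])
        for (r in seq_len(acq$runs_per_condition)) {
          runs[[length(runs) + 1L]] <- generate_run(
            latent_ses, acq,
            noise_scale = config$observation_noise_scale,
            sd_multiplier = sd_mult[[cond]],
            motion = mm,
            seed = derive_seed(config$seed, 3000, si, ses, ci, r),
            subject_id = sub$subject_id, session = ses,
            condition = cond, run = r,
            contamination_scale = config$contamination_scale,
            latent_factor = latent_factor)
        }
      }
    }
  }

  surveys <- simulate_surveys(subjects, acq,
                              seed = derive_seed(config$seed, 4000))
  cohort <- structure(
    list(runs = runs, registry = registry, surveys = surveys,
         config = config, acq = acq),
    class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

session_latent <- function(latent, zshift_scale, seed) {
  if (zshift_scale <= 0) return(latent)
  n <- nrow(latent)
  with_seed(seed, {
    shift <- stats::rnorm(1, sd = zshift_scale)
    z <- atanh(pmin(pmax(latent, -1 + 1e-7), 1 - 1e-7)) + shift
    m <- tanh(z)
    diag(m) <- 1
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      m <- as.matrix(Matrix::nearPD(m, corr = TRUE, maxit = 200)$mat)
      m <- (m + t(m)) / 2
      diag(m) <- 1
    }
    m
  })
}

# Post-session survey simulator: children attend less to low-engagement
# clips and report more drowsiness during them.
simulate_surveys <- function(subjects, acq, seed) {
  drowsy_levels <- c("none", "tired", "sleepy", "difficulty_staying_awake")
  attention_p <- c(non_narrative = 0.9, narrative = 0.85, low_demand = 0.75)
  drowsy_p <- c(non_narrative = 0.1, narrative = 0.15, low_demand = 0.35)
  with_seed(seed, {
    rows <- list()
    for (sub in subjects) {
      for (ses in seq_len(acq$n_sessions)) {
        for (cond in acq$conditions) {
          pa <- if (cond %in% names(attention_p)) attention_p[[cond]] else 0.85
          pd <- if (cond %in% names(drowsy_p)) drowsy_p[[cond]] else 0.2
          if (sub$age_group == "child") pa <- pa - 0.1
          for (r in seq_len(acq$runs_per_condition)) {
            asked <- 3L
            correct <- stats::rbinom(1, asked, pa)
            drowsy <- drowsy_levels[
              1L + stats::rbinom(1, 3, pd)]
            rows[[length(rows) + 1L]] <- data.frame(
              subject_id = sub$subject_id, session = ses,
              condition = cond, run = r,
              correct = correct, asked = asked,
              drowsiness = drowsy, stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a synthetic cohort as delimited text
#'
#' One node x volume TSV per run
#' (`sub-<id>_ses-<n>_cond-<name>_run-<n>_bold.tsv`), a companion confounds
#' TSV per run (`framewise_displacement` plus six motion-parameter columns
#' that reproduce the FD trace under [compute_fd]), per-subject
#' ground-truth latent connectome TSVs, the survey table, and a JSON
#' manifest.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_dir <- file.path(dir, "ground_truth")
  dir.create(truth_dir, showWarnings = FALSE)
  files <- character(0)
  for (ts in cohort$runs) {
    stem <- sprintf("%s_ses-%d_cond-%s_run-%d", ts$subject_id, ts$session,
                    ts$condition, ts$run)
    bold <- file.path(dir, paste0(stem, "_bold.tsv"))
    utils::write.table(
      signif(ts$signal, 8), bold, sep = "\t",
      row.names = FALSE, col.names = FALSE, quote = FALSE)
    conf <- data.frame(framewise_displacement = signif(ts$fd, 8),
                       trans_x = 0, trans_y = signif(cumsum(ts$fd), 8),
                       trans_z = 0, rot_x = 0, rot_y = 0, rot_z = 0)
    conf_path <- file.path(dir, paste0(stem, "_confounds.tsv"))
    utils::write.table(conf, conf_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, basename(bold), basename(conf_path))
  }
  for (reg in cohort$registry) {
    utils::write.table(
      signif(reg$latent, 8),
      file.path(truth_dir, paste0(reg$subject_id, "_latent.tsv")),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$surveys, file.path(dir, "surveys.csv"),
                   row.names = FALSE)
  manifest <- list(
    n_runs = length(cohort$runs),
    subjects = lapply(cohort$registry, function(r)
      list(subject_id = r$subject_id, age_group = r$age_group,
           pair = r$pair,
           motion = unclass(r$motion))),
    acquisition = unclass(cohort$acq),
    network_labels = cohort$config$network_labels,
    seed = cohort$config$seed,
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
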