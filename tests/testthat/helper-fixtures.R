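# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

quiet_motion <- function(baseline_fd = 0.03, burst_prob = 0) {
  motion_model(baseline_fd, burst_prob)
}

small_acq <- function(volumes_per_run = 60, n_sessions = 4,
                      conditions = c("non_narrative", "narrative",
                                     "low_demand"),
                      runs_per_condition = 2) {
  acquisition_spec(tr_seconds = 2, volumes_per_run = volumes_per_run,
                   runs_per_condition = runs_per_condition,
                   n_sessions = n_sessions, conditions = conditions)
}

# A hand-built parcellated run with fully controlled signal and FD.
manual_run <- function(signal, fd = rep(0, ncol(signal)),
                       subject_id = "sub-01", session = 1L,
                       condition = "non_narrative", run = 1L,
                       tr_seconds = 2) {
  structure(
    list(subject_id = subject_id, session = as.integer(session),
         condition = condition, run = as.integer(run),
         signal = signal,
         node_ids = sprintf("node%03d", seq_len(nrow(signal))),
         tr_seconds = tr_seconds, fd = fd),
    class = "parcellated_ts")
}

# Multi-session runs for one subject drawn from (possibly session-specific)
# latent connectomes; one run per session/condition/run slot.
subject_runs <- function(latents, acq, noise_scale = 0,
                         motion = quiet_motion(), seed = 1,
                         subject_id = "sub-01",
                         contamination_scale = 0,
                         burst_prob_override = NULL) {
  runs <- list()
  for (ses in seq_len(acq$n_sessions)) {
    latent <- if (is.list(latents)) latents[[ses]] else latents
    for (ci in seq_along(acq$conditions)) {
      for (r in seq_len(acq$runs_per_condition)) {
        mm <- motion
        if (!is.null(burst_prob_override))
          mm <- motion_model(motion$baseline_fd, burst_prob_override,
                             motion$burst_meanlog, motion$burst_sdlog)
        runs[[length(runs) + 1L]] <- generate_run(
          latent, acq, noise_scale = noise_scale, motion = mm,
          seed = seed * 100000 + ses * 1000 + ci * 10 + r,
          subject_id = subject_id, session = ses,
          condition = acq$conditions[ci], run = r,
          contamination_scale = contamination_scale)
      }
    }
  }
  runs
}

all_true_masks <- function(runs) {
  lapply(runs, function(r) rep(TRUE, ncol(r$signal)))
}

# Independent ICC(2,1) oracle via R's ANOVA machinery: mean squares from a
# two-way fixed-effects fit, never the package's own code path.
icc21_aov_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  d <- data.frame(y = as.vector(tab),
                  subj = factor(rep(seq_len(n), k)),
                  meas = factor(rep(seq_len(k), each = n)))
  ms <- suppressWarnings(anova(lm(y ~ subj + meas, data = d))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Directly simulated split-half edge data (bypasses BOLD simulation) for
# ICC-level properties. Subject deviations from the shared base carry a
# network-block-level component (individual connectome differences are
# network-structured) plus an edge-level component; each half adds shared
# within-block measurement noise plus independent edge noise. Averaging
# edges within a block before the ICC cancels the edge-level noise while
# keeping the block-level subject signal, so pre-averaging is the more
# reliable route.
simulate_split_half_edges <- function(n_subjects = 30, n_networks = 6,
                                      nodes_per_network = 5,
                                      subject_block_sd = 0.15,
                                      subject_edge_sd = 0.1,
                                      shared_block_sd = 0.03,
                                      edge_sd = 0.12, seed = 1) {
  set.seed(seed)
  labels <- rep(sprintf("net%02d", seq_len(n_networks)),
                each = nodes_per_network)
  n_nodes <- length(labels)
  idx <- edge_index(n_nodes)
  block_of_edge <- paste(pmin(labels[idx$i], labels[idx$j]),
                         pmax(labels[idx$i], labels[idx$j]), sep = "|")
  blocks <- unique(block_of_edge)
  half <- function(truth) {
    shared <- rnorm(length(blocks), sd = shared_block_sd)
    names(shared) <- blocks
    truth + shared[block_of_edge] + rnorm(length(truth), sd = edge_sd)
  }
  half_a <- list(); half_b <- list()
  base <- rnorm(nrow(idx), sd = 0.2)
  for (s in seq_len(n_subjects)) {
    blk <- rnorm(length(blocks), sd = subject_block_sd)
    names(blk) <- blocks
    truth <- base + blk[block_of_edge] +
      rnorm(nrow(idx), sd = subject_edge_sd)
    id <- sprintf("sub%02d", s)
    half_a[[id]] <- devectorize_upper(half(truth), n_nodes)
    half_b[[id]] <- devectorize_upper(half(truth), n_nodes)
  }
  list(dataset = split_half_dataset(half_a, half_b, minutes = NA),
       labels = labels)
}
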