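test_that("split scheme validates its partitions", {
  sc <- split_scheme()
  expect_length(sc$pairs, 3)
  expect_error(split_scheme(4, list(list(a = 1:2, b = 2:4))), "disjoint")
  expect_error(split_scheme(4, list(list(a = 1L, b = 2:3))), "cover")
  expect_error(split_scheme(3), "supply")
})

test_that("identical noise-free halves give TRC = 1 everywhere feasible", {
  acq <- small_acq(volumes_per_run = 90, conditions = "one",
                   runs_per_condition = 1)
  tmpl <- block_template(rep(c("a", "b"), each = 6), within_r = 0.5)
  # same seed for every session: all four sessions carry identical data
  one <- generate_run(tmpl, acq, noise_scale = 0, motion = quiet_motion(),
                      seed = 123, session = 1, condition = "one")
  runs <- lapply(1:4, function(s) {
    r <- one; r$session <- s; r
  })
  cv <- split_session_trc(runs, all_true_masks(runs),
                          grid_minutes = c(1, 2, 3))
  expect_equal(cv$trc, rep(1, 3), tolerance = 1e-10)
})

test_that("split TRC approaches the latent edge-vector correlation", {
  # halves generated from two different latent connectomes, long duration:
  # the TRC converges to the correlation of the ground-truth edge vectors
  set.seed(99)
  labels <- rep(sprintf("n%d", 1:5), each = 10)
  la <- generate_latent_connectome(block_template(labels, 0.4), 0.15, 1)
  lb <- generate_latent_connectome(block_template(labels, 0.4), 0.15, 2)
  truth <- cor(vectorize_upper(fisher_z(la)), vectorize_upper(fisher_z(lb)))
  acq <- small_acq(volumes_per_run = 3000, conditions = "one",
                   runs_per_condition = 1)
  runs <- lapply(1:4, function(s) {
    latent <- if (s %in% c(1, 4)) la else lb
    generate_run(latent, acq, noise_scale = 0, motion = quiet_motion(),
                 seed = 500 + s, session = s, condition = "one")
  })
  cv <- split_session_trc(runs, all_true_masks(runs),
                          scheme = split_scheme(4, list(
                            list(a = c(1L, 4L), b = c(2L, 3L)))),
                          grid_minutes = 100)
  expect_equal(cv$trc, truth, tolerance = 0.05)
})

test_that("infeasible durations are missing, feasible ones are not", {
  acq <- small_acq(volumes_per_run = 60, conditions = "one",
                   runs_per_condition = 1)
  tmpl <- block_template(rep(c("a", "b"), each = 4), within_r = 0.5)
  runs <- subject_runs(tmpl, acq, noise_scale = 0.3, seed = 2)
  # each half holds 2 sessions x 60 volumes = 4 minutes
  cv <- split_session_trc(runs, all_true_masks(runs),
                          grid_minutes = c(2, 4, 10))
  expect_false(any(is.na(cv$trc[1:2])))
  expect_true(is.na(cv$trc[3]))
})

test_that("iterative TRC is exactly 1 on duplicated-content data", {
  # every 1-minute chunk holds identical content, so any subset's FC is
  # identical and the reference/residual correlation is 1
  set.seed(14)
  chunk <- matrix(rnorm(10 * 30), 10)
  data <- do.call(cbind, rep(list(chunk), 12))
  cv <- iterative_trc(data, reference_minutes = 2,
                      grid_minutes = c(1, 2), n_iterations = 5,
                      seed = 3, tr_seconds = 2)
  expect_equal(cv$trc, c(1, 1), tolerance = 1e-10)
})

test_that("iterative TRC is reproducible and robust to the seed", {
  acq <- small_acq(volumes_per_run = 150, conditions = "one",
                   runs_per_condition = 1)
  tmpl <- block_template(rep(c("a", "b", "c"), each = 8), within_r = 0.4)
  runs <- subject_runs(tmpl, acq, noise_scale = 0.5, seed = 4)
  masks <- all_true_masks(runs)
  args <- list(runs, masks, reference_minutes = 10,
               grid_minutes = c(2, 4, 6), n_iterations = 50)
  c1 <- do.call(iterative_trc, c(args, seed = 11))
  c1_again <- do.call(iterative_trc, c(args, seed = 11))
  expect_identical(c1$trc, c1_again$trc)
  c2 <- do.call(iterative_trc, c(args, seed = 12))
  expect_equal(c1$trc, c2$trc, tolerance = 0.05)
})

test_that("iterative TRC hovers near zero without latent structure", {
  set.seed(15)
  data <- matrix(rnorm(40 * 1200), 40)   # pure white noise, 780 edges
  cv <- iterative_trc(data, reference_minutes = 6, grid_minutes = 4,
                      n_iterations = 30, seed = 9, tr_seconds = 2)
  expect_lt(abs(cv$trc), 0.1)
})

test_that("infeasible reference flags the whole curve", {
  data <- matrix(rnorm(5 * 60), 5)
  cv <- iterative_trc(data, reference_minutes = 60, grid_minutes = c(5, 10),
                      n_iterations = 3, seed = 1, tr_seconds = 2)
  expect_true(all(is.na(cv$trc)))
  expect_true(attr(cv, "infeasible"))
})

test_that("time to threshold interpolates linearly between grid points", {
  cv <- data.frame(duration_min = c(20, 25), trc = c(0.78, 0.82))
  expect_equal(time_to_threshold(cv, 0.8), 22.5)

  first_hit <- data.frame(duration_min = c(5, 10), trc = c(0.85, 0.9))
  expect_equal(time_to_threshold(first_hit, 0.8), 5)

  low <- data.frame(duration_min = c(5, 10), trc = c(0.7, 0.79))
  res <- time_to_threshold(low, 0.8)
  expect_true(is.na(res))
  expect_identical(attr(res, "reason"), "unreachable")

  gappy <- data.frame(duration_min = c(5, 10, 15),
                      trc = c(NA, 0.7, 0.9))
  expect_equal(time_to_threshold(gappy, 0.8), 12.5)
})

test_that("Cohen's d matches hand arithmetic and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3)), 2)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("incremental benefit telescopes along the curve", {
  flat <- data.frame(duration_min = c(5, 10, 15), trc = c(0.5, 0.5, 0.5))
  expect_equal(incremental_benefit(flat)$delta_trc, c(0, 0))

  cv <- data.frame(duration_min = c(5, 10, 15), trc = c(0.5, 0.7, 0.75))
  inc <- incremental_benefit(cv)
  expect_equal(inc$delta_trc, c(0.2, 0.05))
  expect_equal(inc$duration_min, c(10, 15))
  expect_equal(sum(inc$delta_trc), cv$trc[3] - cv$trc[1])
})

test_that("condition curves agree with the all-condition curve when only
           one condition exists", {
  acq <- small_acq(volumes_per_run = 90, conditions = "one",
                   runs_per_condition = 1)
  tmpl <- block_template(rep(c("a", "b"), each = 5), within_r = 0.5)
  runs <- subject_runs(tmpl, acq, noise_scale = 0.4, seed = 6)
  masks <- all_true_masks(runs)
  whole <- split_session_trc(runs, masks, grid_minutes = c(2, 4))
  one <- condition_trc(runs, masks, "one", grid_minutes = c(2, 4))
  expect_equal(one$trc, whole$trc)
  expect_identical(attr(one, "condition_scope"), "one")

  beyond <- condition_trc(runs, masks, "one", grid_minutes = c(2, 50))
  expect_true(is.na(beyond$trc[2]))
  expect_error(condition_trc(runs, masks, "missing"), "no runs")
})

test_that("noisier conditions are less reliable at matched duration", {
  acq <- acquisition_spec(volumes_per_run = 90,
                          conditions = c("clean", "noisy"))
  tmpl <- block_template(rep(c("a", "b", "c"), each = 6), within_r = 0.4)
  deltas <- vapply(1:8, function(s) {
    runs <- list()
    for (ses in 1:4) for (cond in acq$conditions) for (r in 1:2) {
      ns <- if (cond == "clean") 0.3 else 1.5
      runs[[length(runs) + 1L]] <- generate_run(
        tmpl, acq, noise_scale = ns, motion = quiet_motion(),
        seed = s * 1000 + ses * 100 + match(cond, acq$conditions) * 10 + r,
        session = ses, condition = cond, run = r)
    }
    masks <- all_true_masks(runs)
    clean <- condition_trc(runs, masks, "clean", grid_minutes = c(2, 4, 6))
    noisy <- condition_trc(runs, masks, "noisy", grid_minutes = c(2, 4, 6))
    mean(clean$trc - noisy$trc)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.7)
})

test_that("group summaries aggregate curves and effect sizes", {
  mk <- function(vals) data.frame(duration_min = c(5, 10), trc = vals)
  curves <- list(s1 = mk(c(0.5, 0.7)), s2 = mk(c(0.55, 0.72)),
                 s3 = mk(c(0.3, 0.5)), s4 = mk(c(0.35, 0.52)))
  groups <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
  summ <- summarize_trc(curves, groups, d_pair = c("a", "b"))
  expect_equal(summ$mean_trc[summ$group == "a" & summ$duration_min == 5],
               0.525)
  expect_equal(summ$mean_trc[summ$group == "b" & summ$duration_min == 10],
               0.51)
  expect_true(all(summ$cohens_d > 0))
})
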