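test_that("ICC(2,1) matches the ANOVA oracle on random tables", {
  set.seed(101)
  for (i in 1:100) {
    tab <- matrix(rnorm(10, sd = runif(1, 0.5, 3)), 5, 2)
    expect_equal(icc_2_1(tab), icc21_aov_oracle(tab), tolerance = 1e-10)
  }
})

test_that("ICC(2,1) handles canonical special cases", {
  # identical measurement columns, subjects distinct -> perfect agreement
  tab <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(icc_2_1(tab), 1)

  # the 3x2 toy table: value frozen from the ANOVA oracle (= 8/9)
  toy <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(icc_2_1(toy), icc21_aov_oracle(toy), tolerance = 1e-12)
  expect_equal(icc_2_1(toy), 8 / 9)

  expect_true(is.na(icc_2_1(matrix(2, 4, 2))))
  expect_error(icc_2_1(matrix(1:2, 1, 2)), ">= 2")
  expect_error(icc_2_1(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("ICC is invariant to shift and positive scaling", {
  set.seed(5)
  tab <- matrix(rnorm(20), 10, 2)
  expect_equal(icc_2_1(tab + 100), icc_2_1(tab), tolerance = 1e-12)
  expect_equal(icc_2_1(tab * 7), icc_2_1(tab), tolerance = 1e-12)
})

test_that("vectorized edge ICC equals the per-edge scalar computation", {
  set.seed(55)
  n_sub <- 8; n_nodes <- 6
  half_a <- list(); half_b <- list()
  for (s in 1:n_sub) {
    ma <- matrix(rnorm(n_nodes^2), n_nodes); ma <- (ma + t(ma)) / 2
    mb <- matrix(rnorm(n_nodes^2), n_nodes); mb <- (mb + t(mb)) / 2
    diag(ma) <- diag(mb) <- 0
    half_a[[sprintf("s%d", s)]] <- ma
    half_b[[sprintf("s%d", s)]] <- mb
  }
  ds <- split_half_dataset(half_a, half_b)
  em <- edgewise_icc(ds)
  for (e in sample(nrow(edge_index(n_nodes)), 5)) {
    ij <- edge_index(n_nodes)[e, ]
    tab <- cbind(ds$edges_a[, e], ds$edges_b[, e])
    expect_equal(em[ij$i, ij$j], icc_2_1(tab), tolerance = 1e-12)
  }
  expect_true(all(is.na(diag(em))))
  expect_equal(em, t(em))
})

test_that("edge ICC hits its structural limits", {
  set.seed(56)
  half <- lapply(1:6, function(s) {
    m <- matrix(rnorm(25), 5); m <- (m + t(m)) / 2; diag(m) <- 0; m
  })
  names(half) <- sprintf("s%d", 1:6)
  same <- edgewise_icc(split_half_dataset(half, half))
  expect_equal(same[upper.tri(same)], rep(1, 10), tolerance = 1e-12)

  # no between-subject variance: same truth + iid noise -> ICC near zero
  common <- matrix(rnorm(64), 8); common <- (common + t(common)) / 2
  diag(common) <- 0
  noisy <- function() {
    lapply(setNames(1:30, sprintf("s%d", 1:30)), function(s) {
      m <- common + matrix(rnorm(64, sd = 0.5), 8)
      m <- (m + t(m)) / 2; diag(m) <- 0; m
    })
  }
  ds0 <- split_half_dataset(noisy(), noisy())
  e0 <- edgewise_icc(ds0)
  expect_lt(abs(mean(e0[upper.tri(e0)])), 0.1)
})

test_that("pre-averaged network ICC reduces correctly and ignores node order", {
  sim <- simulate_split_half_edges(n_subjects = 15, n_networks = 3,
                                   nodes_per_network = 4, seed = 2)
  pre <- network_icc_pre_average(sim$dataset, sim$labels)
  expect_equal(pre, t(pre), ignore_attr = TRUE)

  # single network covering all nodes: equals ICC of the per-subject mean
  one <- network_icc_pre_average(sim$dataset,
                                 rep("all", length(sim$labels)))
  manual <- icc_2_1(cbind(rowMeans(sim$dataset$edges_a),
                          rowMeans(sim$dataset$edges_b)))
  expect_equal(one["all", "all"], manual, tolerance = 1e-12)

  # permuting node labels within the same partition leaves blocks unchanged
  perm <- sample(length(sim$labels))
  ds_perm <- split_half_dataset(
    lapply(seq_len(nrow(sim$dataset$edges_a)), function(s)
      devectorize_upper(sim$dataset$edges_a[s, ],
                        length(sim$labels))[perm, perm]),
    lapply(seq_len(nrow(sim$dataset$edges_b)), function(s)
      devectorize_upper(sim$dataset$edges_b[s, ],
                        length(sim$labels))[perm, perm]))
  pre_perm <- network_icc_pre_average(ds_perm, sim$labels[perm])
  expect_equal(pre_perm, pre, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("undersized networks are excluded with a warning", {
  sim <- simulate_split_half_edges(n_subjects = 8, n_networks = 2,
                                   nodes_per_network = 3, seed = 3)
  labels <- c("solo", rep("netA", 2), rep("netB", 3))
  expect_warning(
    pre <- network_icc_pre_average(sim$dataset, labels), "solo")
  expect_true(is.na(pre["solo", "solo"]))
  expect_false(is.na(pre["netA", "netB"]))
})

test_that("post-averaged network ICC is the block mean of edge ICC", {
  # constant edge ICC: every block equals that constant
  n_nodes <- 6
  labels <- rep(c("x", "y"), each = 3)
  const <- devectorize_upper(rep(0.42, 15), n_nodes, diag = NA)
  post <- network_icc_post_average(const, labels)
  expect_equal(unique(as.vector(post)), 0.42)

  # hand-set edge ICC on a 4-node, 2-network toy
  labels4 <- c("a", "a", "b", "b")
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)  # edges 12,13,14,23,24,34
  em <- devectorize_upper(vals, 4, diag = NA)
  post4 <- network_icc_post_average(em, labels4)
  expect_equal(post4["a", "a"], 0.1)               # edge (1,2)
  expect_equal(post4["b", "b"], 0.6)               # edge (3,4)
  expect_equal(post4["a", "b"], mean(c(0.2, 0.3, 0.4, 0.5)))

  # count-weighted block means reproduce the grand edge mean
  counts <- c("a|a" = 1, "a|b" = 4, "b|b" = 1)
  weighted <- (post4["a", "a"] * 1 + post4["a", "b"] * 4 +
                 post4["b", "b"] * 1) / 6
  expect_equal(weighted, mean(vals))
})

test_that("parcel-level summaries follow from the edge matrix", {
  uni <- devectorize_upper(rep(0.37, 3), 3, diag = NA)
  expect_equal(parcelwise_mean_icc(uni), rep(0.37, 3))

  em <- devectorize_upper(c(0.2, 0.4, 0.6), 3, diag = NA)
  expect_equal(parcelwise_mean_icc(em), c(0.3, 0.4, 0.5))
  expect_true(all(parcelwise_mean_icc(em) >= 0.2 &
                    parcelwise_mean_icc(em) <= 0.6))
})

test_that("parcelwise TRC is 1 for identical halves and antisymmetric in
           group differences", {
  set.seed(60)
  half <- lapply(setNames(1:4, sprintf("s%d", 1:4)), function(s) {
    m <- matrix(rnorm(49), 7); m <- (m + t(m)) / 2; diag(m) <- 0; m
  })
  ds_same <- split_half_dataset(half, half)
  expect_equal(parcelwise_trc(ds_same), rep(1, 7), tolerance = 1e-12)

  other <- lapply(half, function(m) m + matrix(rnorm(49, sd = 0.2), 7))
  other <- lapply(other, function(m) {
    m <- (m + t(m)) / 2; diag(m) <- 0; m
  })
  ds <- split_half_dataset(half, other)
  a <- parcelwise_trc(ds)
  expect_true(all(a >= -1 & a <= 1))
  # identical groups difference: zero map
  expect_equal(a - a, rep(0, 7))
})

test_that("ICC categories use contiguous conventional bins", {
  expect_equal(as.character(bin_icc(c(0.3, 0.5, 0.7, 0.8))),
               c("poor", "fair", "good", "excellent"))
  expect_equal(as.character(bin_icc(0.4)), "poor")
  expect_equal(as.character(bin_icc(-0.1)), "poor")
  expect_equal(as.character(bin_icc(0.6)), "good")
  expect_equal(as.character(bin_icc(0.75)), "excellent")
  # full coverage of [-1, 1]
  grid <- seq(-1, 1, by = 0.001)
  expect_false(anyNA(bin_icc(grid)))
  m <- bin_icc(devectorize_upper(c(0.2, 0.5, 0.9), 3, diag = NA))
  expect_true(is.matrix(m))
  expect_identical(m[1, 2], "poor")
})

test_that("split-half construction drops short subjects and keeps durations
           matched", {
  acq <- small_acq(volumes_per_run = 60, conditions = "one",
                   runs_per_condition = 1)
  tmpl <- block_template(rep(c("a", "b"), each = 4), within_r = 0.4)
  rbs <- list(
    long1 = subject_runs(tmpl, acq, noise_scale = 0.4, seed = 11,
                         subject_id = "long1"),
    long2 = subject_runs(tmpl, acq, noise_scale = 0.4, seed = 12,
                         subject_id = "long2"))
  # a third subject with heavy censoring cannot reach the duration
  short_runs <- subject_runs(tmpl, acq, noise_scale = 0.4, seed = 13,
                             subject_id = "short")
  masks <- list(long1 = all_true_masks(rbs$long1),
                long2 = all_true_masks(rbs$long2),
                short = lapply(short_runs, function(r)
                  c(rep(TRUE, 10), rep(FALSE, 50))))
  rbs$short <- short_runs
  ds <- build_split_half(rbs, masks, minutes = 3)
  expect_identical(attr(ds, "dropped"), "short")
  expect_identical(rownames(ds$edges_a), c("long1", "long2"))
  expect_identical(ds$minutes, 3)
})

test_that("network ICC duration sweep reports feasible cells and skips the
           rest", {
  acq <- small_acq(volumes_per_run = 60, conditions = "one",
                   runs_per_condition = 1)
  tmpl <- block_template(rep(c("a", "b"), each = 4), within_r = 0.4)
  rbs <- lapply(setNames(1:4, sprintf("s%d", 1:4)), function(s)
    subject_runs(tmpl, acq, noise_scale = 0.4, seed = 20 + s,
                 subject_id = sprintf("s%d", s)))
  groups <- setNames(rep("g", 4), names(rbs))
  masks <- lapply(rbs, all_true_masks)
  expect_warning(
    sweep <- network_icc_by_duration(rbs, groups, tmpl_labels <- rep(
      c("a", "b"), each = 4), durations = c(2, 50),
      masks_by_subject = masks),
    "skipped")
  expect_true(all(sweep$duration_min == 2))
  expect_setequal(sweep$network, c("a", "b"))
})
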