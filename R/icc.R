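#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' With MSR the between-subjects mean square, MSC the between-measurements
#' mean square, and MSE the residual mean square of the two-way
#' decomposition of an n x k table,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#'
#' @param table Numeric n x k matrix: n subjects, k repeated
#'   measurements, no missing cells.
#' @return ICC value (at most 1; may be negative), or `NA` when the table
#'   is degenerate (all cells identical).
#' @export
icc_2_1 <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 2L || k < 2L) stop_invalid("need >= 2 subjects and >= 2 measures")
  if (anyNA(table)) stop_invalid("missing cells are not allowed")
  grand <- mean(table)
  row_m <- rowMeans(table)
  col_m <- colMeans(table)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((table - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' Bundle per-subject split-half connectomes
#'
#' @param half_a,half_b Named lists (one entry per subject) of Fisher-z
#'   connectivity matrices, each built from the same T post-censored
#'   minutes; halves come from disjoint session sets.
#' @param group Group label (single string) for the dataset.
#' @param minutes Split-half duration T (minutes).
#' @return A `split_half_dataset` holding edge matrices (subjects x
#'   edges) for each half.
#' @export
split_half_dataset <- function(half_a, half_b, group = "all",
                               minutes = NA) {
  stopifnot(length(half_a) == length(half_b), length(half_a) >= 1L)
  ea <- t(vapply(half_a, vectorize_upper,
                 numeric(nrow(half_a[[1L]]) * (nrow(half_a[[1L]]) - 1) / 2)))
  eb <- t(vapply(half_b, vectorize_upper, numeric(ncol(ea))))
  structure(list(edges_a = ea, edges_b = eb,
                 n_nodes = nrow(half_a[[1L]]),
                 subject_ids = names(half_a),
                 group = group, minutes = minutes),
            class = "split_half_dataset")
}

# Vectorized ICC(2,1) for k = 2 across many columns (edges/blocks).
icc21_two_halves <- function(a, b) {
  n <- nrow(a)
  grand <- (colMeans(a) + colMeans(b)) / 2
  subj <- (a + b) / 2
  msr <- 2 * colSums(sweep(subj, 2L, grand)^2) / (n - 1)
  msc <- n * ((colMeans(a) - grand)^2 + (colMeans(b) - grand)^2)
  sst <- colSums(sweep(a, 2L, grand)^2) + colSums(sweep(b, 2L, grand)^2)
  sse <- pmax(sst - (n - 1) * msr - msc, 0)
  mse <- sse / (n - 1)
  denom <- msr + mse + (2 / n) * (msc - mse)
  out <- (msr - mse) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Edge-wise ICC across subjects
#'
#' Feeds each edge's subjects x 2 half table to ICC(2,1).
#'
#' @param dataset A [split_half_dataset] with >= 2 subjects.
#' @return Node x node symmetric matrix of edge ICC values (diagonal
#'   `NA`), with the dataset's group and duration as attributes.
#' @export
edgewise_icc <- function(dataset) {
  stopifnot(inherits(dataset, "split_half_dataset"))
  if (nrow(dataset$edges_a) < 2L) stop_invalid("need >= 2 subjects")
  vals <- icc21_two_halves(dataset$edges_a, dataset$edges_b)
  m <- devectorize_upper(vals, dataset$n_nodes, diag = NA)
  structure(m, group = dataset$group, minutes = dataset$minutes,
            level = "edge")
}

# Edge indices of every network-pair block, in canonical edge order.
block_edge_indices <- function(network_labels) {
  n <- length(network_labels)
  idx <- edge_index(n)
  li <- network_labels[idx$i]
  lj <- network_labels[idx$j]
  a <- pmin(li, lj)
  b <- pmax(li, lj)
  split(idx$edge, paste(a, b, sep = "|"))
}

block_matrix <- function(values_by_block, networks) {
  m <- matrix(NA_real_, length(networks), length(networks),
              dimnames = list(networks, networks))
  for (key in names(values_by_block)) {
    nets <- strsplit(key, "|", fixed = TRUE)[[1L]]
    m[nets[1L], nets[2L]] <- m[nets[2L], nets[1L]] <- values_by_block[[key]]
  }
  m
}

#' Network-wise ICC, averaging edges before the ICC
#'
#' For each subject and half, Fisher-z edges are averaged within every
#' network-pair block; ICC(2,1) is then computed across subjects per
#' block. Averaging first cancels edge-level independent noise, so these
#' values typically exceed the post-averaged ones. Within-network
#' (diagonal) blocks require networks with >= 2 nodes; undersized networks
#' are excluded with a warning.
#'
#' @param dataset A [split_half_dataset].
#' @param network_labels Node-to-network map (length = node count).
#' @return Network x network symmetric ICC matrix (`level =
#'   "network_pre"`).
#' @export
network_icc_pre_average <- function(dataset, network_labels) {
  stopifnot(length(network_labels) == dataset$n_nodes)
  small <- names(which(table(network_labels) < 2L))
  if (length(small))
    warning("network(s) with < 2 nodes excluded from within-network ",
            "blocks: ", paste(small, collapse = ", "), call. = FALSE)
  blocks <- block_edge_indices(network_labels)
  vals <- lapply(blocks, function(cols) {
    a <- rowMeans(dataset$edges_a[, cols, drop = FALSE])
    b <- rowMeans(dataset$edges_b[, cols, drop = FALSE])
    icc_2_1(cbind(a, b))
  })
  nets <- sort(unique(network_labels))
  m <- block_matrix(vals, nets)
  structure(m, group = dataset$group, minutes = dataset$minutes,
            level = "network_pre")
}

#' Network-wise ICC, averaging edge ICC values after computation
#'
#' @param edge_icc Node x node edge ICC matrix from [edgewise_icc].
#' @param network_labels Node-to-network map.
#' @return Network x network matrix of block-mean edge ICC (`level =
#'   "network_post"`).
#' @export
network_icc_post_average <- function(edge_icc, network_labels) {
  stopifnot(nrow(edge_icc) == length(network_labels))
  vals <- vectorize_upper(unname(`diag<-`(as.matrix(edge_icc), 0)))
  blocks <- block_edge_indices(network_labels)
  means <- lapply(blocks, function(cols) mean(vals[cols]))
  nets <- sort(unique(network_labels))
  m <- block_matrix(means, nets)
  structure(m, group = attr(edge_icc, "group"),
            minutes = attr(edge_icc, "minutes"), level = "network_post")
}

#' Mean edge ICC per parcel
#'
#' Averages each node's ICC over its N-1 connections — the per-parcel
#' surface-map summary.
#'
#' @param edge_icc Node x node edge ICC matrix (diagonal ignored).
#' @return Numeric vector, one value per node.
#' @export
parcelwise_mean_icc <- function(edge_icc) {
  m <- as.matrix(edge_icc)
  diag(m) <- NA
  rowMeans(m, na.rm = TRUE)
}

#' Per-parcel test-retest correlation map
#'
#' For each subject and node, correlates the node's half-A connectivity
#' profile (its matrix row, self-connection excluded) with its half-B
#' profile, then averages across subjects.
#'
#' @param dataset A [split_half_dataset].
#' @return Numeric vector of per-node mean TRC in `[-1, 1]`.
#' @export
parcelwise_trc <- function(dataset) {
  n_nodes <- dataset$n_nodes
  n_sub <- nrow(dataset$edges_a)
  acc <- matrix(NA_real_, n_sub, n_nodes)
  for (s in seq_len(n_sub)) {
    a <- devectorize_upper(dataset$edges_a[s, ], n_nodes, diag = NA)
    b <- devectorize_upper(dataset$edges_b[s, ], n_nodes, diag = NA)
    for (i in seq_len(n_nodes))
      acc[s, i] <- stats::cor(a[i, -i], b[i, -i])
  }
  colMeans(acc)
}

#' Categorize ICC values
#'
#' Conventional bins: poor (ICC <= 0.4, including nonpositive values),
#' fair (0.4, 0.6), good `[0.6, 0.75)`, excellent (>= 0.75). The published
#' convention leaves (0.59, 0.6) unmapped; the bins here are contiguous.
#'
#' @param value Numeric vector/matrix of ICC values.
#' @return Factor (or matrix-shaped character) with levels poor, fair,
#'   good, excellent.
#' @export
bin_icc <- function(value) {
  f <- function(v) {
    ifelse(is.na(v), NA_character_,
           ifelse(v <= 0.4, "poor",
                  ifelse(v < 0.6, "fair",
                         ifelse(v < 0.75, "good", "excellent"))))
  }
  if (is.matrix(value)) {
    out <- matrix(f(value), nrow(value), ncol(value),
                  dimnames = dimnames(value))
    return(out)
  }
  factor(f(value), levels = c("poor", "fair", "good", "excellent"))
}

#' Build per-subject split halves at a fixed duration
#'
#' For each subject: concatenate censored runs of each session set of
#' `pair` in acquisition order and build a Fisher-z connectome from the
#' first `minutes` post-censored minutes. Subjects lacking the duration in
#' either half are dropped (returned in `dropped`).
#'
#' @param runs_by_subject Named list: subject id -> list of
#'   `parcellated_ts` runs.
#' @param masks_by_subject Named list of mask lists, parallel to
#'   `runs_by_subject` (default: FD censoring at 0.15 mm).
#' @param minutes Split-half duration (minutes of post-censored data per
#'   half).
#' @param pair Session-set pair, e.g. `list(a = c(1, 4), b = c(2, 3))`.
#' @param group Group label stored on the dataset.
#' @return A [split_half_dataset] (plus attribute `dropped`).
#' @export
build_split_half <- function(runs_by_subject, masks_by_subject = NULL,
                             minutes,
                             pair = list(a = c(1L, 4L), b = c(2L, 3L)),
                             group = "all") {
  if (is.null(masks_by_subject))
    masks_by_subject <- lapply(runs_by_subject, function(rs)
      lapply(rs, function(r) censor(r$fd)))
  half_a <- list(); half_b <- list(); dropped <- character(0)
  for (id in names(runs_by_subject)) {
    runs <- runs_by_subject[[id]]
    masks <- masks_by_subject[[id]]
    tr <- runs[[1L]]$tr_seconds
    sess <- vapply(runs, `[[`, integer(1), "session")
    mk <- function(set) {
      sel <- which(sess %in% set)
      sel_runs <- order_runs(runs[sel])
      sel_masks <- masks[sel][match_run_ids(sel_runs, runs[sel])]
      data <- concat_censored(sel_runs, sel_masks)
      need <- minutes_to_volumes(minutes, tr)
      if (ncol(data) < need) return(NULL)
      fisher_z(pearson_fc(data[, seq_len(need), drop = FALSE]))
    }
    za <- mk(pair$a); zb <- mk(pair$b)
    if (is.null(za) || is.null(zb)) {
      dropped <- c(dropped, id)
      next
    }
    half_a[[id]] <- za
    half_b[[id]] <- zb
  }
  if (!length(half_a))
    stop_invalid("no subject has %g split-half minutes", minutes)
  ds <- split_half_dataset(half_a, half_b, group = group, minutes = minutes)
  attr(ds, "dropped") <- dropped
  ds
}

#' Mean within-network ICC by group and split-half duration
#'
#' Builds split-half datasets at each requested duration per group,
#' computes edge-wise ICC, and reports the mean ICC of each network's
#' within-network block. Group/duration combinations whose data cannot
#' supply the duration are skipped with a warning.
#'
#' @param runs_by_subject Named list: subject id -> run list.
#' @param groups Named character vector: subject id -> group.
#' @param network_labels Node-to-network map.
#' @param durations Split-half durations in minutes (default 5, 10, 24,
#'   54).
#' @param networks Networks to report (default all).
#' @param pair Session-set pair for the split.
#' @param masks_by_subject Optional mask lists.
#' @return Long data frame (group, network, duration_min, mean_icc).
#' @export
network_icc_by_duration <- function(runs_by_subject, groups, network_labels,
                                    durations = c(5, 10, 24, 54),
                                    networks = NULL,
                                    pair = list(a = c(1L, 4L),
                                                b = c(2L, 3L)),
                                    masks_by_subject = NULL) {
  if (is.null(networks)) networks <- sort(unique(network_labels))
  out <- list()
  for (g in unique(groups)) {
    ids <- names(groups)[groups == g]
    for (t in durations) {
      ds <- tryCatch(
        build_split_half(runs_by_subject[ids],
                         if (is.null(masks_by_subject)) NULL
                         else masks_by_subject[ids],
                         minutes = t, pair = pair, group = g),
        error = function(e) NULL)
      if (is.null(ds) || nrow(ds$edges_a) < 2L ||
          length(attr(ds, "dropped"))) {
        warning(sprintf(
          "group '%s' lacks %g split-half minutes for all subjects; skipped",
          g, t), call. = FALSE)
        next
      }
      eicc <- edgewise_icc(ds)
      vals <- vectorize_upper(unname(`diag<-`(as.matrix(eicc), 0)))
      blocks <- block_edge_indices(network_labels)
      for (net in networks) {
        key <- paste(net, net, sep = "|")
        if (!key %in% names(blocks)) next
        out[[length(out) + 1L]] <- data.frame(
          group = g, network = net, duration_min = t,
          mean_icc = mean(vals[blocks[[key]]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(group = character(0),
                                      network = character(0),
                                      duration_min = numeric(0),
                                      mean_icc = numeric(0)))
  do.call(rbind, out)
}
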