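#' Concatenate censored runs into one node x volume matrix
#'
#' Retained volumes only, in acquisition order within each run, runs in the
#' order given. All runs must share the same node set.
#'
#' @param runs List of `parcellated_ts` runs.
#' @param masks List of logical censor masks parallel to `runs` (default:
#'   censor each run's FD at 0.15 mm).
#' @return Node x volume matrix; zero columns (everything censored) are
#'   flagged with attribute `empty = TRUE`.
#' @export
concat_censored <- function(runs,
                            masks = lapply(runs, function(r) censor(r$fd))) {
  stopifnot(length(runs) >= 1L, length(runs) == length(masks))
  ids <- runs[[1L]]$node_ids
  pieces <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (!identical(r$node_ids, ids))
      stop_invalid("run %d has a different node set", i)
    m <- masks[[i]]
    if (length(m) != ncol(r$signal))
      stop_invalid("mask %d length (%d) != run volumes (%d)",
                   i, length(m), ncol(r$signal))
    pieces[[i]] <- r$signal[, m, drop = FALSE]
  }
  out <- do.call(cbind, pieces)
  if (ncol(out) == 0L) attr(out, "empty") <- TRUE
  rownames(out) <- ids
  out
}

#' Pearson correlation connectome
#'
#' @param data Node x volume matrix with at least 3 volumes.
#' @return Node x node correlation matrix (unit diagonal, symmetric).
#' @export
pearson_fc <- function(data) {
  if (!is.matrix(data) || ncol(data) < 3L)
    stop_invalid("need a node x volume matrix with >= 3 volumes")
  sds <- apply(data, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    labs <- if (!is.null(rownames(data))) rownames(data)[bad] else bad
    stop_invalid("zero-variance node(s): %s",
                 paste(labs, collapse = ", "))
  }
  m <- stats::cor(t(data))
  (m + t(m)) / 2
}

#' Fisher z-transformation
#'
#' `z = atanh(r)`, applied elementwise. Off-diagonal values at exactly
#' +/-1 (possible on tiny inputs) are clipped to +/-(1 - 1e-7) with a
#' warning rather than erroring. For matrices the diagonal is set to 0
#' before the transform and excluded from clipping checks.
#'
#' @param r Correlation value, vector, or matrix.
#' @return z value(s) of the same shape.
#' @export
fisher_z <- function(r) {
  if (is.matrix(r)) {
    d <- diag(r)
    diag(r) <- 0
    out <- fisher_z(c(r))
    out <- matrix(out, nrow(r), ncol(r), dimnames = dimnames(r))
    diag(out) <- 0
    return(out)
  }
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop_invalid("correlations must lie in [-1, 1]")
  hit <- abs(r) >= 1 - 1e-12
  hit[is.na(hit)] <- FALSE
  if (any(hit)) {
    warning("correlation(s) at +/-1 clipped before Fisher z", call. = FALSE)
    r[hit] <- sign(r[hit]) * (1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Flatten a symmetric matrix to its canonical edge vector
#'
#' Row-major upper triangle: edges (1,2), (1,3), ..., (1,N), (2,3), ...
#' `devectorize_upper()` inverts the operation (diagonal set to `diag`).
#'
#' @param m Symmetric node x node matrix.
#' @param tol Asymmetry tolerance.
#' @return Numeric vector of length `N(N-1)/2` with attribute `n_nodes`.
#' @export
vectorize_upper <- function(m, tol = 1e-8) {
  check_symmetric(m, "m", tol = tol)
  v <- t(m)[lower.tri(m)]
  attr(v, "n_nodes") <- nrow(m)
  v
}

#' @rdname vectorize_upper
#' @param v Edge vector from `vectorize_upper()`.
#' @param n_nodes Matrix dimension (taken from the vector's attribute when
#'   omitted).
#' @param diag Value placed on the diagonal.
#' @export
devectorize_upper <- function(v, n_nodes = attr(v, "n_nodes"), diag = 0) {
  if (is.null(n_nodes)) stop_invalid("`n_nodes` is required")
  if (length(v) != n_nodes * (n_nodes - 1) / 2)
    stop_invalid("edge vector length does not match n_nodes")
  mt <- matrix(0, n_nodes, n_nodes)
  mt[lower.tri(mt)] <- v          # row-major upper triangle of t(mt)
  m <- t(mt)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  base::diag(m) <- diag
  m
}

#' Map edge-vector positions to node pairs
#'
#' @param n_nodes Matrix dimension.
#' @return Data frame with columns `edge`, `i`, `j` (i < j) in canonical
#'   row-major order.
#' @export
edge_index <- function(n_nodes) {
  i <- rep(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L),
                     function(k) (k + 1L):n_nodes))
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' Per-node temporal mean and standard deviation
#'
#' The numerator (`tmean`) and denominator (`tsd`) of temporal SNR,
#' computed over retained volumes. `tsd` uses the sample (n - 1) SD.
#'
#' @param data Node x volume matrix.
#' @return Named numeric vector, one value per node.
#' @export
tmean <- function(data) {
  stopifnot(is.matrix(data))
  rowMeans(data)
}

#' @rdname tmean
#' @export
tsd <- function(data) {
  stopifnot(is.matrix(data), ncol(data) >= 2L)
  apply(data, 1L, stats::sd)
}

#' Descriptive OLS relation between two per-node maps
#'
#' Fits `y ~ x` across nodes (e.g., a change in test-retest correlation
#' against a change in temporal mean signal) and reports slope, intercept,
#' r, and the slope p-value.
#'
#' @param x,y Numeric vectors of equal length (one value per node).
#' @return List with `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
map_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = unname(sign(stats::coef(fit)[2L]) * sqrt(s$r.squared)),
       p_value = unname(s$coefficients[2L, 4L]),
       n = length(x))
}
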