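#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("`%s` must be a single positive finite number", name)
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_invalid("`%s` must be a single nonnegative finite number", name)
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x))
    stop_invalid("`%s` must be a positive integer", name)
  invisible(as.integer(x))
}

is_square_matrix <- function(m) {
  is.matrix(m) && nrow(m) == ncol(m)
}

check_symmetric <- function(m, name, tol = 1e-8) {
  if (!is_square_matrix(m))
    stop_invalid("`%s` must be a square matrix", name)
  if (max(abs(m - t(m))) > tol)
    stop_invalid("`%s` must be symmetric (tolerance %g)", name, tol)
  invisible(m)
}

check_correlation_matrix <- function(m, name, psd_tol = 1e-8) {
  check_symmetric(m, name)
  if (max(abs(diag(m) - 1)) > 1e-8)
    stop_invalid("`%s` must have a unit diagonal", name)
  if (any(m < -1 - 1e-8) || any(m > 1 + 1e-8))
    stop_invalid("`%s` entries must lie in [-1, 1]", name)
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -psd_tol)
    stop_invalid("`%s` must be positive semidefinite (min eigenvalue %g)",
                 name, ev)
  invisible(m)
}

# Deterministic child seed derivation, kept < 2^31 so it is a valid R seed.
# The multiplier keeps h * 69069 below 2^53, so the arithmetic is exact in
# doubles.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 104729
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 12345) %% 2147483647
  as.integer(h)
}

# Evaluate an expression under a local RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
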