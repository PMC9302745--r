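# Internal helpers shared across modules.

#' Derive a child RNG seed from a root seed
#'
#' Hierarchical seeding: every simulated data set (and every stochastic
#' stage within it) gets its own reproducible stream derived from a root
#' seed and a small index, so grid cells can be re-run independently.
#' The derived seed always stays inside the 32-bit signed integer range.
#'
#' @param seed integer root seed.
#' @param index non-negative integer index of the child stream.
#' @return an integer seed usable with [set.seed()].
#' @export
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # multiplicative hash modulo a Mersenne prime; keeps streams well separated
  m <- 2147483647
  s <- (abs(seed) %% m)
  s <- (s * 48271 + (index %% m) * 16807 + 11) %% m
  as.integer(s + 1)
}

# geometric mean of a strictly positive vector
geo_mean <- function(x) exp(mean(log(x)))

# normalize a positive vector so its geometric mean is 1
geo_mean_one <- function(x) {
  stopifnot(all(x > 0))
  x / geo_mean(x)
}

# adjusted Fisher-Pearson skewness (the G1 statistic)
skewness_g1 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# row variances of a matrix, denominator n - 1
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
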