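# Paired absolute/observed count simulator.
#
# The generative model: baseline log mean abundances are log-normal;
# a second condition perturbs them with a multivariate normal whose
# covariance is a (rescaled) inverse-Wishart correlation matrix; a
# random subset of features keeps the perturbed mean ("truly"
# differential); replicate counts are drawn negative-binomially with
# per-sample scale noise; finally every sample is resampled
# multinomially to one fixed common depth, which destroys all
# information about total abundance and yields compositional
# ("observed") counts.

#' Specify the feature-correlation structure of perturbations
#'
#' Perturbations of log mean abundance between conditions are drawn from
#' a multivariate normal whose correlation matrix is itself drawn from an
#' inverse-Wishart distribution and rescaled to unit diagonal. The scale
#' matrix is either the identity (independent features) or a
#' block-exchangeable matrix with a positively correlated block.
#'
#' @param kind `"identity"` or `"dense-positive"`.
#' @param df inverse-Wishart degrees of freedom; must exceed P + 1.
#'   `NULL` (default) resolves at draw time to `2 * P + 50`, which keeps
#'   sampling noise on the realized correlations small while preserving
#'   the block structure of the scale matrix.
#' @param strength off-diagonal value inside the correlated block
#'   (ignored for `"identity"`).
#' @param frac_correlated fraction of features in the correlated block,
#'   in \[0, 0.5\].
#' @return an object of class `correlation_spec`.
#' @export
correlation_spec <- function(kind = c("identity", "dense-positive"),
                             df = NULL, strength = 0.5,
                             frac_correlated = 0.25) {
  kind <- match.arg(kind)
  if (!is.null(df)) stopifnot(is.finite(df), df > 0)
  stopifnot(strength >= 0, strength < 1,
            frac_correlated >= 0, frac_correlated <= 0.5)
  structure(list(kind = kind, df = df, strength = strength,
                 frac_correlated = frac_correlated),
            class = "correlation_spec")
}

#' Five canonical correlation presets
#'
#' Presets span fully independent features at one extreme and 50% of
#' features strongly positively correlated at the other.
#'
#' @param level integer 1 (independent) to 5 (50% at strength 0.9).
#' @return a [correlation_spec()].
#' @export
correlation_preset <- function(level) {
  stopifnot(level %in% 1:5)
  switch(level,
    correlation_spec("identity"),
    correlation_spec("dense-positive", strength = 0.3, frac_correlated = 0.125),
    correlation_spec("dense-positive", strength = 0.5, frac_correlated = 0.25),
    correlation_spec("dense-positive", strength = 0.7, frac_correlated = 0.375),
    correlation_spec("dense-positive", strength = 0.9, frac_correlated = 0.5))
}

#' All generative hyperparameters of one simulated data set
#'
#' @param P number of features (>= 2).
#' @param m baseline log mean abundance (natural log scale).
#' @param S baseline log standard deviation (>= 0).
#' @param corr a [correlation_spec()].
#' @param a perturbation variance scale (>= 0); the covariance of the
#'   between-condition log perturbation is `a` times the correlation
#'   matrix, so the typical per-feature log perturbation has standard
#'   deviation `sqrt(a)`.
#' @param c target proportion of differentially abundant features.
#' @param g standard deviation of the per-sample scale multiplier
#'   `delta = max(0.1, N(1, g))`.
#' @param R replicates per condition (>= 2, default 10).
#' @param d_abs negative binomial size (dispersion) parameter of the
#'   absolute counts; the default 1000 makes counts barely overdispersed
#'   relative to Poisson (variance = mu + mu^2/1000).
#' @param depth_lo,depth_hi bounds of the uniform draw of the common
#'   observed sequencing depth.
#' @param seed integer RNG seed for this data set.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(P, m = 5, S = 2, corr = correlation_spec(),
                              a = 1, c = 0.5, g = 0.2, R = 10L,
                              d_abs = 1000, depth_lo = 5000,
                              depth_hi = 2e6, seed = 1L) {
  stopifnot(P >= 2, is.finite(m), S >= 0,
            inherits(corr, "correlation_spec"),
            a >= 0, c >= 0, c <= 1, g >= 0, R >= 2,
            d_abs > 0, depth_lo >= 1, depth_lo <= depth_hi)
  structure(list(P = as.integer(P), m = m, S = S, corr = corr, a = a,
                 c = c, g = g, R = as.integer(R), d_abs = d_abs,
                 depth_lo = depth_lo, depth_hi = depth_hi,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw baseline log mean abundances
#'
#' @param P number of features.
#' @param m,S mean and standard deviation of the normal draw.
#' @return length-P numeric vector of i.i.d. Normal(m, S^2) draws.
#' @export
draw_baseline_log_means <- function(P, m, S) {
  stopifnot(P >= 1, is.finite(m), S >= 0)
  stats::rnorm(P, mean = m, sd = S)
}

# analytic inverse of an exchangeable-block scale matrix:
# Q = I except a leading B x B block with off-diagonal rho
.block_scale_matrix <- function(P, frac, rho) {
  B <- round(frac * P)
  Q <- diag(P)
  if (B >= 2 && rho > 0) {
    Q[seq_len(B), seq_len(B)] <- rho
    diag(Q)[seq_len(B)] <- 1
  }
  Q
}

#' Draw a feature-correlation matrix
#'
#' Draws `Omega ~ Inverse-Wishart(df, Q)` with `Q` built from `corr`,
#' then rescales to a correlation matrix `D^{-1/2} Omega D^{-1/2}`.
#'
#' @param P number of features.
#' @param corr a [correlation_spec()].
#' @return P x P symmetric positive definite matrix with unit diagonal.
#' @export
build_correlation <- function(P, corr = correlation_spec()) {
  stopifnot(inherits(corr, "correlation_spec"), P >= 1)
  df <- corr$df %||% (2 * P + 50)
  if (df <= P + 1) stop("inverse-Wishart df must exceed P + 1")
  Q <- .block_scale_matrix(P,
                           if (corr$kind == "identity") 0 else corr$frac_correlated,
                           if (corr$kind == "identity") 0 else corr$strength)
  Qinv <- chol2inv(chol(Q))
  # W ~ Wishart(df, Q^{-1})  =>  W^{-1} ~ Inverse-Wishart(df, Q)
  W <- stats::rWishart(1L, df = df, Sigma = Qinv)[, , 1L]
  Omega <- chol2inv(chol(W))
  d <- 1 / sqrt(diag(Omega))
  Omega <- Omega * tcrossprod(d)
  diag(Omega) <- 1
  (Omega + t(Omega)) / 2
}

#' Perturb log mean abundances for the second condition
#'
#' One multivariate normal draw with mean `theta1` and covariance
#' `a * Omega`.
#'
#' @param theta1 baseline log means.
#' @param Omega correlation matrix (unit diagonal, positive definite).
#' @param a covariance scale (>= 0).
#' @return perturbed log mean vector of the same length as `theta1`.
#' @export
perturb_log_means <- function(theta1, Omega, a) {
  P <- length(theta1)
  stopifnot(a >= 0, is.matrix(Omega), nrow(Omega) == P, ncol(Omega) == P)
  if (a == 0) return(theta1)
  L <- chol(Omega)
  theta1 + sqrt(a) * drop(crossprod(L, stats::rnorm(P)))
}

#' Select differential features and form per-condition mean vectors
#'
#' Each feature is flagged differential independently with probability
#' `c`; flagged features take the perturbed mean in condition 2, all
#' others keep the baseline mean in both conditions.
#'
#' @param theta1,theta2 baseline and perturbed log mean vectors.
#' @param c probability a feature is differential.
#' @return list with `truth` (logical), `mu1`, `mu2` (positive means on
#'   the count scale).
#' @export
select_differential <- function(theta1, theta2, c) {
  stopifnot(length(theta1) == length(theta2), c >= 0, c <= 1)
  truth <- stats::runif(length(theta1)) < c
  mu1 <- exp(theta1)
  mu2 <- ifelse(truth, exp(theta2), mu1)
  list(truth = truth, mu1 = mu1, mu2 = mu2)
}

#' Draw one per-sample scale multiplier
#'
#' @param g standard deviation of the normal draw; the multiplier is
#'   `max(0.1, N(1, g))`, floored so samples never lose more than 90%
#'   of their material.
#' @param n number of multipliers to draw.
#' @return numeric vector of length `n`.
#' @export
draw_sample_multiplier <- function(g, n = 1L) {
  stopifnot(g >= 0, n >= 1)
  pmax(0.1, stats::rnorm(n, mean = 1, sd = g))
}

#' Draw absolute counts for one sample
#'
#' Independent negative binomial draws with mean `mu * delta` and size
#' `d_abs` (variance = mean + mean^2 / d_abs).
#'
#' @param mu per-feature mean vector (>= 0).
#' @param delta per-sample scale multiplier.
#' @param d_abs negative binomial size.
#' @return integer-valued count vector.
#' @export
draw_absolute_counts <- function(mu, delta, d_abs = 1000) {
  stopifnot(all(mu >= 0), d_abs > 0, delta > 0)
  y <- numeric(length(mu))
  pos <- mu > 0
  y[pos] <- stats::rnbinom(sum(pos), mu = mu[pos] * delta, size = d_abs)
  y
}

#' Draw the common observed sequencing depth
#'
#' @param depth_lo,depth_hi uniform bounds.
#' @return one integer-rounded uniform draw, shared by all samples of a
#'   data set.
#' @export
draw_observed_depth <- function(depth_lo = 5000, depth_hi = 2e6) {
  stopifnot(depth_lo >= 1, depth_lo <= depth_hi)
  round(stats::runif(1, depth_lo, depth_hi))
}

#' Multinomially resample one sample to a fixed depth
#'
#' @param y absolute count vector with positive total.
#' @param u target depth (>= 1).
#' @return count vector summing exactly to `u`.
#' @export
multinomial_resample <- function(y, u) {
  stopifnot(u >= 1)
  if (sum(y) <= 0) stop("cannot resample an all-zero sample")
  drop(stats::rmultinom(1L, size = u, prob = y / sum(y)))
}

#' Simulate one paired absolute/observed data set
#'
#' Runs the full generative model: baseline log means, inverse-Wishart
#' correlated perturbation, differential selection, negative binomial
#' replicate counts with per-sample scale noise, and fixed-depth
#' multinomial resampling. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a list of class `paired_count_data` with elements `Y`
#'   (absolute counts, P x 2R), `Z` (observed counts, P x 2R, all
#'   column sums equal to `depth`), `condition` (1/2 labels), `truth`,
#'   `mu1`, `mu2`, `depth`, `delta` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  P <- config$P; R <- config$R
  n <- 2L * R
  condition <- rep(1:2, each = R)

  set.seed(derive_seed(config$seed, 1L))
  theta1 <- draw_baseline_log_means(P, config$m, config$S)

  set.seed(derive_seed(config$seed, 2L))
  Omega <- build_correlation(P, config$corr)

  set.seed(derive_seed(config$seed, 3L))
  theta2 <- perturb_log_means(theta1, Omega, config$a)

  set.seed(derive_seed(config$seed, 4L))
  sel <- select_differential(theta1, theta2, config$c)

  set.seed(derive_seed(config$seed, 5L))
  delta <- draw_sample_multiplier(config$g, n)
  Y <- matrix(0, nrow = P, ncol = n)
  for (i in seq_len(n)) {
    mu <- if (condition[i] == 1L) sel$mu1 else sel$mu2
    Y[, i] <- draw_absolute_counts(mu, delta[i], config$d_abs)
  }

  set.seed(derive_seed(config$seed, 6L))
  u <- draw_observed_depth(config$depth_lo, config$depth_hi)
  Z <- matrix(0, nrow = P, ncol = n)
  for (i in seq_len(n)) {
    if (sum(Y[, i]) == 0) {
      # pathological sample with no material at all: resample uniformly
      Z[, i] <- multinomial_resample(rep(1, P), u)
    } else {
      Z[, i] <- multinomial_resample(Y[, i], u)
    }
  }

  rn <- paste0("f", seq_len(P))
  cn <- paste0("s", seq_len(n))
  dimnames(Y) <- dimnames(Z) <- list(rn, cn)
  structure(list(Y = Y, Z = Z, condition = condition, truth = sel$truth,
                 mu1 = sel$mu1, mu2 = sel$mu2, depth = u, delta = delta,
                 config = config),
            class = "paired_count_data")
}

#' @export
print.paired_count_data <- function(x, ...) {
  cat(sprintf(paste0("paired_count_data: %d features x %d samples ",
                     "(%d per condition)\n"),
              nrow(x$Y), ncol(x$Y), x$config$R))
  cat(sprintf("  observed depth: %d; %d/%d features truly differential\n",
              x$depth, sum(x$truth), length(x$truth)))
  invisible(x)
}

#' Filter low-abundance features from a matrix pair
#'
#' Keeps features whose mean count is at least `min_mean` in both the
#' absolute and the observed table (boundary inclusive).
#'
#' @param Y,Z matrices sharing the feature dimension.
#' @param truth optional logical vector subset alongside.
#' @param min_mean minimum mean count (default 1).
#' @return list with filtered `Y`, `Z`, `truth` and the logical `keep`
#'   vector.
#' @export
filter_low_abundance <- function(Y, Z, truth = NULL, min_mean = 1) {
  stopifnot(nrow(Y) == nrow(Z))
  keep <- rowMeans(Y) >= min_mean & rowMeans(Z) >= min_mean
  if (!any(keep)) stop("all features removed by the abundance filter")
  list(Y = Y[keep, , drop = FALSE], Z = Z[keep, , drop = FALSE],
       truth = if (!is.null(truth)) truth[keep] else NULL, keep = keep)
}
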