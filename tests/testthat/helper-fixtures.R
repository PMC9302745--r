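# Shared fixtures and independent mini-oracles used across test files.

# small paired data set, deterministic
toy_sim <- function(seed = 42, P = 150, c = 0.5, a = 2, g = 0.2,
                    corr_level = 3, m = 4, S = 1.5) {
  simulate_dataset(simulation_config(
    P = P, m = m, S = S, corr = correlation_preset(corr_level),
    a = a, c = c, g = g, seed = seed))
}

# independent quadratic-time step-up BH oracle
bh_brute <- function(p) {
  n <- length(p)
  q <- rep(NA_real_, n)
  ok <- which(!is.na(p))
  m <- length(ok)
  for (i in ok) {
    # q_i = min over thresholds t >= p_i of t * m / rank(t)
    cand <- sapply(ok, function(j) {
      if (p[j] >= p[i]) p[j] * m / sum(p[ok] <= p[j]) else Inf
    })
    q[i] <- min(1, min(cand))
  }
  q
}

# independent Spearman: Pearson correlation of midranks
spearman_brute <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# two-group NB count matrix with known means and size factors
null_nb_matrix <- function(P, n_per_group, mu, size = 1000, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  matrix(stats::rnbinom(P * n, mu = rep(mu, n), size = size), nrow = P)
}
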