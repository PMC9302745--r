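# Size-factor strategies: identities, toy recoveries, and independent
# package cross-checks (edgeR / DESeq2 as reference implementations).

test_that("total-count factors are proportional column totals", {
  Z <- cbind(rep(10, 10), rep(10, 10))
  expect_equal(size_factors_total(Z)$values, c(1, 1))
  Z2 <- cbind(c(60, 40), c(250, 150))
  expect_equal(size_factors_total(Z2)$values, c(0.5, 2))
  expect_equal(size_factors_total(matrix(5, 3, 1))$values, 1)
  expect_error(size_factors_total(cbind(c(1, 1), c(0, 0))))
})

test_that("TMM factors ignore pure depth and resist a single jumping feature", {
  Z <- matrix(rpois(200, 50), 100, 2)
  Z[, 2] <- Z[, 1]
  expect_equal(size_factors_tmm(Z)$values, c(1, 1))
  Zb <- cbind(Z[, 1], 2 * Z[, 1])        # doubled depth, same composition
  f <- size_factors_tmm(Zb)$values
  expect_equal(f[2] / f[1], 1, tolerance = 1e-10)
  # one feature jumps 100-fold; the stable features carry equal counts,
  # so the TMM-corrected effective depth ratio is ~1 while raw totals
  # claim a 20-fold difference
  Zc <- cbind(c(100, 100, 100, 100, 100), c(100, 100, 100, 100, 10000))
  tmm <- size_factors_tmm(Zc)$values
  totals <- colSums(Zc)
  eff <- totals * tmm
  expect_lt(abs(log(eff[2] / eff[1])), 0.2)
  expect_gt(abs(log(totals[2] / totals[1])), 3)
})

test_that("TMM agrees with edgeR's implementation on random data", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  Z <- matrix(rnbinom(200 * 10, mu = rep(exp(rnorm(200, 3, 1.5)), 10),
                      size = 10), ncol = 10)
  mine <- size_factors_tmm(Z)$values
  ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = Z),
                                method = "TMM")$samples$norm.factors
  ref <- ref / exp(mean(log(ref)))
  expect_lt(max(abs(mine / ref - 1)), 0.10)
})

test_that("median-of-ratios factors recover pure scalings and match DESeq2", {
  Z <- matrix(rpois(300, 30) + 1, 100, 3)
  Z[, 2] <- Z[, 1]; Z[, 3] <- Z[, 1]
  expect_equal(size_factors_median_ratio(Z)$values, rep(1, 3))
  Z2 <- cbind(Z[, 1], 3 * Z[, 1])
  f <- size_factors_median_ratio(Z2)$values
  expect_equal(f[2] / f[1], 3, tolerance = 1e-12)
  expect_error(size_factors_median_ratio(rbind(c(1, 0), c(0, 1))),
               "positive in all")

  skip_if_not_installed("DESeq2")
  set.seed(22)
  Z3 <- matrix(rnbinom(200 * 8, mu = rep(exp(rnorm(200, 3, 1)), 8),
                       size = 10), ncol = 8) + 1
  mine <- size_factors_median_ratio(Z3)$values
  ref <- DESeq2::estimateSizeFactorsForMatrix(Z3)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(mine, unname(ref), tolerance = 1e-8)
})

test_that("control features rescue median-of-ratios under heavy compositional change", {
  set.seed(23)
  P <- 100; n <- 10
  base <- exp(rnorm(P, 4, 1)) + 5
  scale_true <- exp(seq(-0.5, 0.5, length.out = n))
  Z <- sapply(1:n, function(i) {
    mu <- base * scale_true[i]
    mu[1:60] <- mu[1:60] * ifelse(i > 5, 8, 1)  # 60% features shifted up
    rpois(P, mu)
  })
  controls <- 61:100
  f <- size_factors_median_ratio(Z, controls = controls)$values
  truth <- scale_true / exp(mean(log(scale_true)))
  expect_lt(max(abs(f / truth - 1)), 0.10)
})

test_that("deconvolution recovers known per-sample factors", {
  Z <- matrix(rpois(400, 40) + 1, 100, 4)
  for (j in 2:4) Z[, j] <- Z[, 1]
  expect_equal(size_factors_deconvolution(Z)$values, rep(1, 4),
               tolerance = 1e-8)
  set.seed(24)
  n <- 20
  base <- exp(rnorm(500, 4, 1))
  truth <- exp(seq(log(1), log(8), length.out = n))
  Z2 <- sapply(1:n, function(i) rpois(500, base * truth[i]))
  f <- size_factors_deconvolution(Z2)$values
  truth_n <- truth / exp(mean(log(truth)))
  expect_lt(max(abs(f / truth_n - 1)), 0.05)
  expect_true(all(f > 0))
})

test_that("bias-correction offsets recover a known sampling-fraction ratio", {
  Z <- matrix(rpois(200, 100) + 50, 50, 4)
  Z[, 2] <- Z[, 1]; Z[, 4] <- Z[, 3]
  f0 <- size_factors_bias_correction(Z, c(1, 1, 2, 2))$values
  expect_equal(f0, rep(1, 4), tolerance = 0.05)
  A <- rpois(50, 200) + 100
  Z2 <- cbind(A, A, 5 * A, 5 * A)
  f <- size_factors_bias_correction(Z2, c(1, 1, 2, 2))$values
  expect_lt(abs(f[3] / f[1] / 5 - 1), 0.02)
  # geometric-mean-1 convention fixes the identifiability constant
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("all strategies agree with total-count factors when nothing changes", {
  # c = 0: no differential features, hence no compositional distortion
  sim <- toy_sim(seed = 25, P = 200, c = 0, a = 2, g = 0.3)
  tot <- size_factors_total(sim$Z)$values
  for (f in list(size_factors_tmm(sim$Z)$values,
                 size_factors_median_ratio(sim$Z)$values,
                 size_factors_deconvolution(sim$Z, sim$condition)$values,
                 size_factors_bias_correction(sim$Z, sim$condition)$values)) {
    expect_lt(max(abs(f / tot - 1)), 0.05)
  }
})

test_that("rescaling factors track the true scale better than totals under change", {
  # one-sided widespread change: observed totals are misleading
  set.seed(26)
  P <- 300; n <- 20; cond <- rep(1:2, each = 10)
  mu <- exp(rnorm(P, 4, 1))
  up <- 1:150
  Y <- sapply(1:n, function(i) {
    m <- mu
    if (cond[i] == 2) m[up] <- m[up] * 6
    rpois(P, m)
  })
  u <- 5e4
  Z <- sapply(1:n, function(i) multinomial_resample(Y[, i], u))
  # true relative scale of observed vs absolute counts per sample
  truth <- u / colSums(Y)
  truth <- truth / exp(mean(log(truth)))
  rmse <- function(f) sqrt(mean((log(f) - log(truth))^2))
  e_tot <- rmse(size_factors_total(Z)$values)
  expect_lt(rmse(size_factors_tmm(Z)$values), e_tot)
  expect_lt(rmse(size_factors_median_ratio(Z)$values), e_tot)
  expect_lt(rmse(size_factors_deconvolution(Z, cond)$values), e_tot)
})
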