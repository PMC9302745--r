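# Differential testing: BH adjustment, the NB GLM engine (vs a
# brute-force oracle and vs MASS::glm.nb), the CLR Monte-Carlo test,
# and the calling policies.

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(31)
  for (n in c(3, 17, 50)) {
    p <- round(runif(n), 3)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  p <- c(0.01, NA, 0.5)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  # order invariance
  p2 <- runif(20)
  o <- sample(20)
  expect_equal(bh_adjust(p2)[o], bh_adjust(p2[o]))
})

test_that("calling policies threshold q and fold change monotonically", {
  res <- data.frame(q = c(0.049, 0.001, 0.2), log2fc = c(2, 0.5, 3))
  expect_equal(call_features(res, call_policy(0.05, 0)),
               c(TRUE, TRUE, FALSE))
  expect_equal(call_features(res, call_policy(0.05, 1)),
               c(TRUE, FALSE, FALSE))
  # the stringent policy never adds calls
  set.seed(32)
  res2 <- data.frame(q = runif(200), log2fc = rnorm(200, 0, 2))
  lenient <- call_features(res2, call_policy(0.05, 0))
  stringent <- call_features(res2, call_policy(0.01, 1))
  expect_true(all(lenient[stringent]))
})

test_that("NB GLM null p-values are uniform and effects are recovered", {
  mu <- exp(runif(2000, 2, 6))
  Y <- null_nb_matrix(2000, 40, mu, seed = 33)
  r <- nb_glm_test(Y, rep(1:2, each = 40))
  ks <- suppressWarnings(ks.test(r$p, "punif"))
  expect_gt(ks$p.value, 0.01)

  # group means 100 vs 400: log2 fold change 2, R = 10, dispersion 1000
  set.seed(34)
  P <- 300
  Y2 <- cbind(matrix(rnbinom(P * 10, mu = 100, size = 1000), P),
              matrix(rnbinom(P * 10, mu = 400, size = 1000), P))
  r2 <- nb_glm_test(Y2, rep(1:2, each = 10))
  expect_lt(abs(median(r2$log2fc) - 2), 0.1)
  expect_gt(mean(r2$called), 0.99)

  # all-zero features: p = 1, never called, flagged
  Y3 <- rbind(Y2[1:3, ], 0)
  r3 <- nb_glm_test(Y3, rep(1:2, each = 10))
  expect_equal(r3$p[4], 1)
  expect_false(r3$called[4])
  expect_equal(r3$flag[4], "allzero")
  # one group all zero is handled with a pseudo-count and flagged
  Y4 <- rbind(c(rep(0, 10), rpois(10, 50)), Y2[1:2, ])
  r4 <- nb_glm_test(Y4, rep(1:2, each = 10))
  expect_equal(r4$flag[1], "pseudo")
  expect_true(is.finite(r4$p[1]) && r4$p[1] < 0.05)
})

test_that("NB GLM engine matches MASS::glm.nb per-feature fits", {
  skip_if_not_installed("MASS")
  set.seed(35)
  P <- 30; n <- 20; cond <- rep(1:2, each = 10)
  mu <- exp(rnorm(P, 4, 1)); fc <- exp(rnorm(P, 0, 0.7))
  Y <- sapply(1:n, function(i) {
    rnbinom(P, mu = mu * ifelse(cond[i] == 2, fc, 1), size = 20)
  })
  sf <- exp(rnorm(n, 0, 0.2))
  sf <- sf / exp(mean(log(sf)))
  mine <- nb_glm_test(Y, cond, sf)
  ref <- t(sapply(seq_len(P), function(p) {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ x + offset(o),
        data = data.frame(y = Y[p, ], x = factor(cond), o = log(sf)))),
      error = function(e) NULL)
    if (is.null(fit)) return(c(NA, NA))
    s <- summary(fit)$coefficients
    c(s[2, 1] / log(2), s[2, 4])
  }))
  ok <- is.finite(ref[, 1])
  expect_gt(sum(ok), 25)
  expect_lt(max(abs(mine$log2fc[ok] - ref[ok, 1])), 1e-4)
  expect_lt(max(abs(log10(mine$p[ok]) - log10(ref[ok, 2]))), 1e-3)
})

test_that("NB GLM approaches the Poisson fit as dispersion vanishes", {
  set.seed(36)
  P <- 50; cond <- rep(1:2, each = 10)
  Y <- matrix(rpois(P * 20, 60), P)
  r <- nb_glm_test(Y, cond)
  zref <- sapply(seq_len(P), function(p) {
    f <- glm(Y[p, ] ~ factor(cond), family = poisson())
    summary(f)$coefficients[2, 3]
  })
  zmine <- qnorm(r$p / 2, lower.tail = FALSE) * sign(r$log2fc)
  expect_gt(cor(zmine, zref), 0.99)
})

test_that("CLR Monte-Carlo test finds a spiked feature and respects scale invariance", {
  # identical groups of identical columns: nothing called
  Z0 <- matrix(rep(rpois(100, 50), 8), 100)
  r0 <- clr_mc_test(Z0, rep(1:2, each = 4), n_mc = 64)
  expect_gt(min(r0$q), 0.5)
  expect_gt(median(r0$q), 0.9)
  expect_false(any(r0$called))
  expect_error(clr_mc_test(Z0, rep(1:2, each = 4), n_mc = 1))

  # one feature 16-fold up in an otherwise unchanged composition
  set.seed(37)
  base <- exp(rnorm(100, 3, 1)) + 5
  Z <- sapply(1:20, function(i) {
    mu <- base
    if (i > 10) mu[1] <- mu[1] * 16
    rpois(100, mu)
  })
  r <- clr_mc_test(Z, rep(1:2, each = 10), n_mc = 64)
  expect_equal(which.min(r$q), 1L)
  expect_gt(r$log2fc[1], 2)

  # per-sample depth rescaling: the CLR removes depth exactly, the
  # Dirichlet posterior almost (its precision tracks the counts), so
  # conclusions are stable under heterogeneous library sizes
  set.seed(38)
  fac <- runif(20, 0.5, 2)
  Zr <- round(sweep(Z, 2, fac, "*"))
  set.seed(38); r1 <- clr_mc_test(Z, rep(1:2, each = 10), n_mc = 64)
  set.seed(38); rr <- clr_mc_test(Zr, rep(1:2, each = 10), n_mc = 64)
  expect_equal(which.min(rr$q), 1L)
  expect_gt(cor(r1$q, rr$q), 0.9)
})

test_that("run_method dispatches strategies deterministically", {
  sim <- toy_sim(seed = 39, P = 120, c = 0.3, a = 1.5)
  expect_error(run_method(sim$Z, sim$condition, "nope"))
  a <- run_method(sim$Z, sim$condition, "clr_mc", seed = 5, n_mc = 16)
  b <- run_method(sim$Z, sim$condition, "clr_mc", seed = 5, n_mc = 16)
  expect_identical(a, b)
  for (m in c("total_glm", "tmm_glm", "median_ratio_glm",
              "deconvolution_glm", "bias_correction_glm")) {
    r <- run_method(sim$Z, sim$condition, m)
    expect_true(all(r$p >= 0 & r$p <= 1, na.rm = TRUE))
    expect_true(all(r$q >= r$p - 1e-12, na.rm = TRUE))
  }
})

test_that("the absolute-data oracle recovers large simulated effects", {
  # >= 4-fold effects at R = 10: oracle sensitivity vs simulation truth
  set.seed(40)
  P <- 200
  mu1 <- exp(rnorm(P, 4, 1))
  truth <- runif(P) < 0.3
  mu2 <- mu1 * ifelse(truth, ifelse(runif(P) < 0.5, 4, 0.25), 1)
  Y <- cbind(sapply(1:10, function(i) rnbinom(P, mu = mu1, size = 1000)),
             sapply(1:10, function(i) rnbinom(P, mu = mu2, size = 1000)))
  r <- nb_glm_test(Y, rep(1:2, each = 10))
  sens <- sum(r$called & truth) / sum(truth)
  expect_gt(sens, 0.95)
})
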