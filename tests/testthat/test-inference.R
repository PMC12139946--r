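test_that("correlation test reproduces the hold-out inference line", {
  # r = .19 at n = 102: one-sided p < .05, 95% CI [-0.00, 0.37] to 2 d.p.
  set.seed(3)
  z <- matrix(rnorm(102 * 2), ncol = 2)
  x <- z[, 1]
  y <- 0.19 * scale(x)[, 1] + sqrt(1 - 0.19^2) *
    scale(resid(lm(z[, 2] ~ x)))[, 1]
  y <- y * 1 # cor(x, y) is now exactly .19 by construction
  expect_equal(cor(x, y), 0.19, tolerance = 1e-12)
  ct <- correlation_test(x, y, alternative = "greater")
  expect_equal(round(ct$ci_upper, 2), 0.37)
  expect_lt(abs(ct$ci_lower), 0.005)
  expect_lt(ct$p, 0.05)
  expect_equal(ct$p, pt(0.19 * sqrt(100 / (1 - 0.19^2)), 100,
                        lower.tail = FALSE))
})

test_that("Fisher interval is symmetric about zero at r = 0", {
  x <- seq_len(100)
  y <- rep(c(-1, 1), 50)                 # exactly uncorrelated with x? verify
  y <- y - mean(y)
  y <- resid(lm(y ~ x))                  # force r = 0
  ct <- correlation_test(x, y, alternative = "two.sided")
  expect_equal(ct$r, 0, tolerance = 1e-12)
  expect_equal(ct$ci_upper, -ct$ci_lower)
  expect_equal(ct$ci_upper, 0.196, tolerance = 0.005)
})

test_that("perfect correlation yields a degenerate interval", {
  ct <- correlation_test(1:10, 2 * (1:10) + 3)
  expect_equal(ct$r, 1)
  expect_equal(ct$ci_lower, 1)
  expect_equal(ct$ci_upper, 1)
  expect_equal(ct$p, 0)
  expect_error(correlation_test(rep(1, 10), rnorm(10)), "Constant")
  expect_error(correlation_test(1:3, 3:1), "at least 4")
})

test_that("Fisher interval covers zero at the nominal rate under the null", {
  covered <- vapply(1:2000, function(i) {
    set.seed(i)
    x <- rnorm(102); y <- rnorm(102)
    ct <- correlation_test(x, y, alternative = "greater")
    ct$ci_lower <= 0 && ct$ci_upper >= 0
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.015)
})

test_that("correlation Bayes factor agrees with an independent quadrature", {
  skip_if_not_installed("pracma")
  for (case in list(list(r = .19, n = 102, alt = "greater", k = 1 / 3),
                    list(r = .5, n = 100, alt = "greater", k = 1),
                    list(r = -.2, n = 50, alt = "two.sided", k = 1 / 3))) {
    a <- 1 / case$k
    l0 <- braintrait:::correlation_loglik(0, case$r, case$n)
    dens <- function(rho) dbeta((rho + 1) / 2, a, a) / 2
    lims <- if (case$alt == "greater") c(0, 1) else c(-1, 1)
    mass <- if (case$alt == "greater") 1 - pbeta(0.5, a, a) else 1
    f <- function(rho) {
      exp(braintrait:::correlation_loglik(rho, case$r, case$n) - l0) *
        dens(rho) / mass
    }
    oracle <- pracma::quadgk(Vectorize(f), lims[1] + 1e-12, lims[2] - 1e-12,
                             tol = 1e-12)
    got <- correlation_bf(case$r, case$n, case$alt, kappa = case$k)
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("Bayes factor quadrature matches Monte-Carlo prior integration", {
  # one-sided uniform prior: average the likelihood ratio over prior draws
  set.seed(99)
  rho <- runif(1e6)                       # kappa = 1, truncated to (0, 1)
  ll <- braintrait:::correlation_loglik(seq(0, 0.999, length.out = 4001),
                                        0.5, 100)
  # interpolate the smooth log-likelihood rather than evaluating 1e6 times
  lr <- exp(stats::approx(seq(0, 0.999, length.out = 4001), ll, xout = rho,
                          rule = 2)$y -
              braintrait:::correlation_loglik(0, 0.5, 100))
  mc <- mean(lr)
  expect_equal(correlation_bf(0.5, 100, "greater", kappa = 1), mc,
               tolerance = 0.01)
})

test_that("the reduced likelihood matches the sampling density of r", {
  # simulate the distribution of the sample correlation and compare the
  # density ratio at the observed value with the analytic likelihood ratio
  set.seed(12)
  n <- 40; B <- 60000
  sim_r <- function(rho) {
    vapply(seq_len(B), function(i) {
      x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      cor(x, y)
    }, numeric(1))
  }
  r_obs <- 0.3
  d0 <- density(sim_r(0), from = r_obs, to = r_obs, n = 1)$y
  d1 <- density(sim_r(0.4), from = r_obs, to = r_obs, n = 1)$y
  analytic <- exp(braintrait:::correlation_loglik(0.4, r_obs, n) -
                    braintrait:::correlation_loglik(0, r_obs, n))
  expect_equal(d1 / d0, analytic, tolerance = 0.12)
})

test_that("two-sided BF is the prior-mass-weighted mix of one-sided BFs", {
  for (k in c(1, 1 / 3)) {
    bf2 <- correlation_bf(0.25, 80, "two.sided", kappa = k)
    bfg <- correlation_bf(0.25, 80, "greater", kappa = k)
    bfl <- correlation_bf(0.25, 80, "less", kappa = k)
    expect_equal(bf2, 0.5 * bfg + 0.5 * bfl, tolerance = 1e-7)
  }
  # evidence favors the null for r = 0 at large n
  expect_lt(correlation_bf(0, 200, "two.sided", kappa = 1), 1)
  expect_error(correlation_bf(0.5, 100, kappa = 2), "kappa")
})

test_that("Holm adjustment equals the hand-stepped procedure", {
  expect_equal(holm_correct(c(.01, .03, .04)), c(.03, .06, .06))
  expect_equal(holm_correct(0.02), 0.02)
  expect_equal(holm_correct(rep(1, 5)), rep(1, 5))
  # oracle: step down by hand for random families, including declared
  # family sizes larger than the vector
  hand_holm <- function(p, m) {
    o <- order(p)
    adj <- pmin(1, (m - seq_along(p) + 1) * p[o])
    adj <- cummax(adj)
    out <- numeric(length(p))
    out[o] <- adj
    out
  }
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    m <- length(p) + sample(0:3, 1)
    expect_equal(holm_correct(p, m), hand_holm(p, m))
  }
  expect_error(holm_correct(c(.5, 2)), "0, 1")
})

test_that("Holm-adjusted p-values are monotone and no smaller than raw", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(6)
    adj <- holm_correct(p)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("the hold-out power analysis is reproduced", {
  expect_gte(power_correlation(102, 0.30, alpha = 0.05), 0.90)
  expect_equal(power_correlation(102, 0, alpha = 0.05), 0.05)
  pw <- vapply(seq(20, 400, 20), power_correlation, numeric(1), rho = 0.3)
  expect_true(all(diff(pw) > 0))
})

test_that("Spearman-Brown correction follows its closed form", {
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(1 / 3), 0.5)
  expect_error(spearman_brown(-1), "-1")
})
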