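test_that("unit-trait correlations recover exact and null relations", {
  set.seed(4)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("u", 1:4)))
  trait <- x[, 2]
  res <- region_trait_correlations(x, trait)
  expect_equal(res$r[res$unit == "u2"], 1)
  expect_true(all(res$p_holm >= res$p, na.rm = TRUE))
  # zero-variance unit flagged, family shrinks accordingly
  x2 <- cbind(x, u5 = 1)
  res2 <- region_trait_correlations(x2, trait)
  expect_true(is.na(res2$r[res2$unit == "u5"]))
  expect_match(res2$note[res2$unit == "u5"], "zero variance")
  expect_error(region_trait_correlations(x, trait, family_size = 2),
               "smaller")
})

test_that("Holm keeps the family-wise error of network screens at level", {
  hits <- vapply(1:500, function(s) {
    set.seed(s)
    nm <- matrix(rnorm(40 * 7), 40, 7)
    trait <- rnorm(40)
    any(region_trait_correlations(nm, trait, family_size = 7)$p_holm < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.07)     # binomial noise above the nominal .05
})

test_that("region-restricted pattern prediction finds consistent planted signal", {
  co <- tiny_cohort()
  at <- co$atlas
  x <- map_matrix(co$contrasts$scenes_control)
  # plant an all-positive pattern in region 1 tied to a synthetic trait
  keep <- at$region == 1
  set.seed(6)
  trait <- rnorm(nrow(x))
  x2 <- x
  x2[, keep] <- x2[, keep] + 2 * trait
  res <- region_pattern_predict(x2, at, 1, trait,
                                cv_spec(outer_folds = 4, inner_folds = 3,
                                        repeats = 1, seed = 2))
  expect_gt(res$sign_consistency, 0.9)
  expect_gt(res$cv$r_mean, 0.5)
  # null region: no consistent signs, near-zero performance
  res0 <- region_pattern_predict(x, at, 2, trait,
                                 cv_spec(outer_folds = 4, inner_folds = 3,
                                         repeats = 1, seed = 2))
  expect_lt(res0$cv$r_mean, 0.3)
  expect_error(region_pattern_predict(x, at, 999, trait), "out of range")
})

test_that("single-voxel regions reduce to simple regression predictions", {
  set.seed(13)
  v <- rnorm(40)
  trait <- 0.8 * v + rnorm(40, sd = 0.5)
  at <- structure(list(region = c(1L, 2L), network = c(1L, 1L),
                       region_names = c("a", "b"), network_names = "n",
                       coords = cbind(0:1, 0L, 0L), grid = c(2L, 1L, 1L)),
                  class = "brain_atlas")
  x <- cbind(v, rnorm(40))
  # PLS on one voxel is univariate regression: cross-validated predictions
  # must match the closed-form least-squares fit per training fold
  spec <- cv_spec(outer_folds = 4, inner_folds = 0, repeats = 1, seed = 3,
                  grids = list(pls = 1))
  cv <- fit_nested_cv(x[, 1, drop = FALSE], trait, "pls", spec,
                      standardize = FALSE)
  folds <- braintrait:::make_folds(40, 4, braintrait:::child_seed(3, 1))
  for (k in 1:4) {
    tr <- folds != k
    fit <- lm(trait[tr] ~ v[tr])
    manual <- coef(fit)[1] + coef(fit)[2] * v[!tr]
    got <- cv$predictions$predicted[cv$predictions$index %in% which(!tr)]
    expect_equal(unname(got), unname(manual), tolerance = 1e-8)
  }
})

test_that("best-region split-half selects the truly informative region", {
  picks <- vapply(1:20, function(s) {
    set.seed(s)
    rm <- matrix(rnorm(60 * 10), 60, 10,
                 dimnames = list(NULL, paste0("r", 1:10)))
    trait <- rm[, 4] + rnorm(60, sd = 0.6)
    res <- best_region_splithalf(rm, trait, seed = s)
    c(res$unit == "r4", res$r_test > 0)
  }, logical(2))
  expect_gt(mean(picks[1, ]), 0.9)
  expect_true(all(picks[2, picks[1, ]]))
})

test_that("split-half selection does not inflate the confirmatory error", {
  rej <- vapply(1:400, function(s) {
    set.seed(s)
    rm <- matrix(rnorm(60 * 20), 60, 20)
    best_region_splithalf(rm, rnorm(60), seed = s)$p_test < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("split-half runs at the minimal sample size", {
  set.seed(1)
  res <- best_region_splithalf(matrix(rnorm(16), 8, 2), rnorm(8), seed = 1)
  expect_equal(res$n_test, 4)
})

test_that("network models recover linear and non-linear structure", {
  set.seed(10)
  nm <- matrix(rnorm(120 * 7), 120, 7,
               dimnames = list(NULL, paste0("net", 1:7)))
  # exact linear combination: R^2 = 1
  trait_lin <- 2 * nm[, 1] - nm[, 3]
  reg <- suppressWarnings(   # summary.lm warns about the perfect fit
    network_models(nm, trait_lin, "multiple_regression"))
  expect_equal(reg$r_squared, 1)
  expect_lt(reg$p, 1e-10)
  # threshold interaction: the forest beats the linear model's CV fit
  trait_nl <- as.numeric(nm[, 1] > 0 & nm[, 2] > 0) + rnorm(120, sd = 0.3)
  rf <- network_models(nm, trait_nl, "random_forest_oob", n_perm = 99,
                       seed = 2)
  lin_cv <- fit_nested_cv(nm, trait_nl, "pcr",
                          cv_spec(outer_folds = 5, inner_folds = 0,
                                  repeats = 1, seed = 1,
                                  grids = list(pcr = 7)),
                          standardize = FALSE, warn_constant = FALSE)
  expect_gt(rf$r_oob, lin_cv$r_mean)
  expect_lt(rf$p, 0.05)
})

test_that("forest permutation p-values are uniform under the null", {
  ps <- vapply(1:60, function(s) {
    set.seed(s)
    nm <- matrix(rnorm(40 * 7), 40, 7)
    network_models(nm, rnorm(40), "random_forest_oob", n_perm = 49,
                   num_trees = 150, seed = s)$p
  }, numeric(1))
  # discrete grid of (1+b)/50: check the empirical CDF is close to uniform
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("signature expression is the dot product and is linear", {
  expect_equal(signature_expression(matrix(c(2, 1), 1, 2), c(1, -1)), 1)
  set.seed(14)
  x <- matrix(rnorm(10 * 5000), 10, 5000)
  w <- rnorm(5000)
  # brute-force summation oracle
  manual <- vapply(1:10, function(i) sum(w * x[i, ]), numeric(1))
  expect_equal(signature_expression(x, w), manual)
  # linearity
  y <- matrix(rnorm(10 * 5000), 10, 5000)
  expect_equal(signature_expression(2 * x + 3 * y, w),
               2 * signature_expression(x, w) + 3 * signature_expression(y, w))
  # shift invariance for zero-sum weights
  w0 <- w - mean(w)
  expect_equal(signature_expression(x + 5, w0), signature_expression(x, w0))
  expect_error(signature_expression(x, w[-1]), "voxels")
})

test_that("spatial similarity behaves like a correlation over voxels", {
  set.seed(15)
  a <- rnorm(5000)
  expect_equal(spatial_similarity(a, a), 1)
  expect_equal(spatial_similarity(a, -a), -1)
  expect_lt(abs(spatial_similarity(a, rnorm(5000))), 0.05)
  expect_error(spatial_similarity(rep(1, 10), rnorm(10)), "Constant")
  expect_error(spatial_similarity(a, a[-1]), "aligned")
})
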