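test_that("generated atlases partition the grid into contiguous parcels", {
  cfg <- sim_config(grid_shape = c(10, 10, 10), n_regions = 8, n_networks = 2)
  at <- generate_atlas(cfg)
  expect_equal(sort(unique(at$region)), 1:8)
  expect_true(all(tabulate(at$region, 8) > 0))
  expect_equal(length(at$network), 8)
  expect_true(all(at$network %in% 1:2))
  # contiguity: each region's voxels form one 6-connected component
  for (r in 1:8) {
    comp <- braintrait:::grid_components(at$coords[at$region == r, , drop = FALSE])
    expect_equal(max(comp), 1)
  }
})

test_that("degenerate atlases and impossible partitions behave", {
  cfg <- sim_config(grid_shape = c(3, 2, 1), n_regions = 6, n_networks = 2)
  at <- generate_atlas(cfg)
  expect_equal(sort(tabulate(at$region, 6)), rep(1L, 6))   # singleton regions
  expect_error(sim_config(grid_shape = c(2, 2, 1), n_regions = 6),
               "at least")
})

test_that("atlas generation is deterministic and tags theory regions", {
  a1 <- generate_atlas(sim_config(seed = 5))
  a2 <- generate_atlas(sim_config(seed = 5))
  expect_identical(a1, a2)
  expect_true(all(c("amygdala_L", "amygdala_R", "anterior_insula_L",
                    "dACC_L") %in% a1$region_names))
  expect_equal(a1$network_names[7], "somatomotor")
})

test_that("identical configurations generate bit-identical cohorts", {
  c1 <- generate_cohort(sim_config(n_subjects = 20, n_trials_neg = 4,
                                   n_trials_neu = 4, grid_shape = c(5, 5, 4),
                                   n_regions = 10, seed = 77))
  c2 <- generate_cohort(sim_config(n_subjects = 20, n_trials_neg = 4,
                                   n_trials_neu = 4, grid_shape = c(5, 5, 4),
                                   n_regions = 10, seed = 77))
  expect_identical(c1$trial_maps$data, c2$trial_maps$data)
  expect_identical(c1$traits, c2$traits)
  expect_identical(c1$truth$w_trait, c2$truth$w_trait)
})

test_that("cohort invariants hold: shared voxel space, ratings in range", {
  co <- tiny_cohort()
  expect_equal(ncol(co$trial_maps$data),
               ncol(co$contrasts$scenes_control$data))
  expect_true(all(co$ratings$rating >= 1 & co$ratings$rating <= 5))
  expect_true(all(co$ratings$subject %in% co$traits$subject))
  # contrast maps are exactly the negative-minus-neutral trial means
  x <- co$trial_maps$data
  obs <- co$trial_maps$obs
  s <- 3
  neg <- obs$subject == s & obs$condition == "negative"
  neu <- obs$subject == s & obs$condition == "neutral"
  expect_equal(co$contrasts$scenes_control$data[s, ],
               colMeans(x[neg, ]) - colMeans(x[neu, ]))
})

test_that("a large global offset drives between-network correlations up", {
  cfg <- sim_config(n_subjects = 300, grid_shape = c(8, 8, 8),
                    n_regions = 24, sigma_global = 2, beta_trait = 0,
                    seed = 31)
  co <- generate_cohort(cfg)
  nm <- aggregate_maps(co$contrasts$scenes_control, co$atlas, "network")
  cc <- cor(nm)
  expect_gte(mean(cc[upper.tri(cc)]), 0.6)
})

test_that("without trait signal the cross-validated trait r is nil on average", {
  rs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_subjects = 50, n_trials_neg = 3, n_trials_neu = 3,
                      grid_shape = c(6, 6, 6), n_regions = 16,
                      beta_trait = 0, reactivity_trait_cor = 0,
                      seed = 200 + s)
    co <- generate_cohort(cfg)
    x <- scale_images(map_matrix(co$contrasts$scenes_control), "center")
    fit_nested_cv(x, co$traits$vulnerability, "pls",
                  cv_spec(outer_folds = 4, inner_folds = 2, repeats = 1,
                          seed = s, grids = list(pls = c(2, 5))),
                  warn_constant = FALSE)$r_mean
  }, numeric(1))
  expect_lte(mean(rs), 0.05)
})

test_that("a noiseless generator decodes ratings essentially perfectly", {
  # only Likert rounding separates the rating from the latent state
  co <- generate_cohort(sim_config(
    n_subjects = 20, n_trials_neg = 8, n_trials_neu = 8,
    grid_shape = c(5, 5, 4), n_regions = 10, sigma_noise = 0,
    rating_noise = 0, sigma_global = 0, sigma_network = 0,
    sigma_baseline = 0, beta_trait = 0, seed = 9))
  wp <- within_person_decode(
    co$trial_maps,
    spec = cv_spec(outer_folds = 4, inner_folds = 0, repeats = 1, seed = 1,
                   grids = list(pls = 1)))
  expect_gt(wp$mean_r, 0.95)
})

test_that("halving reliability attenuates the observable brain-trait link", {
  r_at <- function(rel) {
    mean(vapply(1:6, function(s) {
      co <- generate_cohort(sim_config(
        n_subjects = 80, n_trials_neg = 4, n_trials_neu = 4,
        grid_shape = c(6, 6, 6), n_regions = 16, reliability = rel,
        seed = 400 + s))
      expr <- signature_expression(
        scale_images(map_matrix(co$contrasts$scenes_control), "center"),
        co$truth$w_trait)
      cor(expr, co$traits$vulnerability)
    }, numeric(1)))
  }
  expect_gt(r_at(0.9), r_at(0.45))
})

test_that("synthetic signatures are unit norm with exact target similarity", {
  co <- tiny_cohort()
  s0 <- generate_signature(co, "fear", spatial_r = 0)
  expect_equal(sqrt(sum(s0$weights^2)), 1, tolerance = 1e-9)
  expect_lt(abs(spatial_similarity(s0$weights, co$truth$w_state)), 1e-10)
  s1 <- generate_signature(co, "sadness", spatial_r = 1)
  expect_equal(spatial_similarity(s1$weights, co$truth$w_state), 1,
               tolerance = 1e-9)
  s5 <- generate_signature(co, "anger", spatial_r = 0.5)
  expect_equal(spatial_similarity(s5$weights, co$truth$w_state), 0.5,
               tolerance = 1e-9)
  expect_error(generate_signature(co, "fear", spatial_r = 1.2), "-1, 1")
  # independent random weight vectors on thousands of voxels decorrelate
  set.seed(2)
  expect_lt(abs(cor(rnorm(5000), rnorm(5000))), 0.05)
})
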