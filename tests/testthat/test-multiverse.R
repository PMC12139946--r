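test_that("staged design grids have the preregistered sizes", {
  g1 <- build_design_grid(1)
  expect_equal(nrow(g1), 12)          # 2 tasks x 2 baselines x 3 scalings
  expect_equal(unique(g1$outcome), "neuroticism")
  expect_equal(unique(g1$algorithm), "pls")
  g2 <- build_design_grid(2)
  expect_equal(nrow(g2), 252)         # 12 x 7 outcomes x 3 algorithms
  expect_equal(length(unique(g2$outcome)), 7)
  g3 <- build_design_grid(3)
  expect_equal(nrow(g3), 1176)        # 12 x 14 outcomes x 7 algo-sample combos
  expect_equal(length(unique(g3$outcome)), 14)
  expect_false(any(g3$algorithm == "pcarf" & g3$sample == "full"))
})

test_that("grid overrides follow factorial arithmetic and validate levels", {
  g <- build_design_grid(2, overrides = list(outcome = "vulnerability"))
  expect_equal(nrow(g), 36)
  g2 <- build_design_grid(1, overrides = list(task = "scenes",
                                              scaling = c("none", "center")))
  expect_equal(nrow(g2), 4)
  expect_error(build_design_grid(2, overrides = list(scaling = "quantile")),
               "Unknown level")
  expect_error(build_design_grid(1, overrides = list(foo = "bar")),
               "Unknown design factor")
  expect_error(build_design_grid(2, available_outcomes = "nope"),
               "available")
})

test_that("the sweep records ten fold rows per design point", {
  co <- tiny_cohort()
  grid <- build_design_grid(1, overrides = list(
    task = "scenes", scaling = c("none", "center")))
  spec <- cv_spec(outer_folds = 5, inner_folds = 0, repeats = 2, seed = 7,
                  grids = list(pls = 3))
  tbl <- run_multiverse(grid, co, spec)
  expect_equal(nrow(tbl), nrow(grid) * 10)
  expect_true(all(table(tbl$model_id) == 10))
  expect_false(any(tbl$failed))
  summ <- summarise_multiverse(tbl)
  expect_equal(nrow(summ), nrow(grid))
})

test_that("identical design points give identical results under one seed", {
  co <- tiny_cohort()
  grid <- build_design_grid(1, overrides = list(
    task = "scenes", baseline = "control", scaling = "center"))
  grid2 <- dplyr::bind_rows(grid, grid)
  grid2$model_id <- 1:2
  spec <- cv_spec(outer_folds = 3, inner_folds = 0, repeats = 1, seed = 3,
                  grids = list(pls = 3))
  tbl <- run_multiverse(grid2, co, spec)
  expect_equal(tbl$r[tbl$model_id == 1], tbl$r[tbl$model_id == 2])
})

test_that("the signal-carrying facet wins the outcome ranking", {
  grid <- build_design_grid(2, overrides = list(
    task = "scenes", baseline = "control", scaling = "center",
    algorithm = "pls"))
  spec <- cv_spec(outer_folds = 5, inner_folds = 0, repeats = 2, seed = 10,
                  grids = list(pls = 10))
  per_seed <- lapply(41:43, function(s) {
    co <- generate_cohort(reduced_sim_config(seed = s, n_subjects = 300))
    summarise_multiverse(run_multiverse(grid, co, spec))
  })
  rank <- dplyr::bind_rows(per_seed) |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(r = mean(.data$r_mean)) |>
    dplyr::arrange(dplyr::desc(r))
  expect_equal(rank$outcome[1], "vulnerability")
})

test_that("failures are isolated to their design point", {
  co <- tiny_cohort()
  grid <- build_design_grid(1, overrides = list(task = "scenes",
                                                scaling = "center"))
  co2 <- co
  co2$contrasts$scenes_implicit <- NULL   # sabotage one branch
  spec <- cv_spec(outer_folds = 3, inner_folds = 0, repeats = 1, seed = 1,
                  grids = list(pls = 2))
  expect_message(tbl <- run_multiverse(grid, co2, spec), "failed")
  expect_true(any(tbl$failed))
  ok <- tbl[!tbl$failed, ]
  expect_equal(unique(ok$baseline), "control")
  expect_error(run_multiverse(grid[0, ], co, spec), "Empty")
})

test_that("design importance ranks a planted factor first and nulls at zero", {
  set.seed(9)
  n_per <- 10
  grid <- tidyr::expand_grid(task = c("scenes", "faces"),
                             scaling = c("none", "center", "zscore"),
                             outcome = c("a", "b", "c", "d"),
                             rep = 1, fold = seq_len(n_per))
  grid$r <- rnorm(nrow(grid), sd = 0.05) + ifelse(grid$outcome == "a", 0.2, 0)
  grid$failed <- FALSE
  imp <- design_importance(grid, num_trees = 300, seed = 2)
  expect_equal(imp$factor[1], "outcome")
  null_imps <- imp$importance_rmse[imp$factor %in% c("task", "scaling")]
  expect_lt(max(abs(null_imps)), 0.02)
  # a single-level factor gets exactly zero importance
  grid$sample <- "training"
  imp2 <- design_importance(grid, num_trees = 300, seed = 2)
  expect_equal(unname(imp2$importance_rmse[imp2$factor == "sample"]), 0)
})

test_that("variance decomposition recovers planted factor SDs", {
  set.seed(17)
  grid <- tidyr::expand_grid(task = paste0("t", 1:2),
                             outcome = paste0("o", 1:8),
                             algorithm = paste0("a", 1:4),
                             fold = 1:10)
  eff_o <- rnorm(8, sd = 0.1)
  grid$r <- eff_o[as.integer(factor(grid$outcome))] +
    rnorm(nrow(grid), sd = 0.05)
  grid$failed <- FALSE
  vd <- variance_decomposition(grid)
  expect_equal(vd$sd[vd$component == "outcome"], 0.1, tolerance = 0.35)
  expect_lt(vd$sd[vd$component == "task"], 0.03)
  expect_equal(vd$sd[vd$component == "residual"], 0.05, tolerance = 0.05)
  # variance components approximately add up to the total variance
  expect_equal(sum(vd$variance), var(grid$r), tolerance = 0.15)
  # residual SD cannot exceed the total SD
  expect_lte(vd$sd[vd$component == "residual"], sd(grid$r))
})

test_that("degenerate decompositions are handled explicitly", {
  grid <- tidyr::expand_grid(task = c("scenes", "faces"),
                             outcome = c("a", "b"), fold = 1:5)
  grid$r <- 0.2
  grid$failed <- FALSE
  vd <- variance_decomposition(grid)
  expect_true(all(vd$sd == 0))
  # aliased factors are refused with a message naming the pair
  grid2 <- grid
  grid2$r <- rnorm(nrow(grid2))
  grid2$algorithm <- ifelse(grid2$task == "scenes", "pls", "svr")
  expect_error(variance_decomposition(grid2), "confounded")
})

test_that("multiverse export writes a CSV and a self-contained HTML table", {
  co <- tiny_cohort()
  grid <- build_design_grid(1, overrides = list(task = "scenes",
                                                baseline = "control"))
  spec <- cv_spec(outer_folds = 3, inner_folds = 0, repeats = 1, seed = 2,
                  grids = list(pls = 2))
  tbl <- run_multiverse(grid, co, spec)
  csv <- tempfile(fileext = ".csv")
  html <- tempfile(fileext = ".html")
  export_multiverse(tbl, csv, html)
  expect_true(file.exists(csv))
  re <- read.csv(csv)
  expect_equal(nrow(re), nrow(tbl))
  page <- readLines(html)
  expect_true(any(grepl("<table>", page)))
  expect_true(any(grepl("zscore", page)))
  unlink(c(csv, html))
})
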