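# Shared fixtures, generated in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# very small cohort for fast unit tests
tiny_cohort <- function(seed = 1, ...) {
  key <- paste0("tiny_", seed, "_", rlang::hash(list(...)))
  cached(key, generate_cohort(sim_config(
    n_subjects = 60, n_trials_neg = 8, n_trials_neu = 8,
    grid_shape = c(6, 6, 6), n_regions = 16, seed = seed, ...)))
}

# the reduced evaluation profile
small_cohort <- function(seed = 1, ...) {
  key <- paste0("small_", seed, "_", rlang::hash(list(...)))
  cached(key, generate_cohort(reduced_sim_config(seed = seed, ...)))
}

# deterministic toy maps: planted linear signal in the first k voxels
toy_problem <- function(n = 60, p = 40, k = 10, beta = 1, noise = 1,
                        seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    w <- c(rep(beta, k), rep(0, p - k))
    y <- drop(x %*% w) + rnorm(n, sd = noise)
    list(x = x, y = y, w = w)
  })
}
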