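# Theory-driven battery: unit-wise correlations with Holm correction,
# region-restricted pattern prediction, the data-driven best-region split-half
# confirmation, multivariate network models, and signature expression.

#' Correlate region or network averages with a trait
#'
#' Pearson correlation of every unit (column) with the trait, two-sided
#' p-values, and Holm adjustment across an explicitly declared family size
#' (the caller states the preregistered family, e.g. six region tests or
#' seven network tests; it is never inferred).
#'
#' @param unit_means observations-by-units matrix (from [aggregate_maps()]) or
#'   data frame with named columns.
#' @param trait numeric outcome.
#' @param family_size declared Holm family size; defaults to the number of
#'   testable units and cannot be smaller than it.
#' @param conf_level level of the per-unit Fisher-z interval.
#' @return a tibble with `unit`, `r`, `p`, `p_holm`, `ci_lower`, `ci_upper`,
#'   `n`, and `note` (zero-variance units are flagged and excluded from the
#'   family).
#' @export
region_trait_correlations <- function(unit_means, trait, family_size = NULL,
                                      conf_level = 0.95) {
  x <- as.matrix(unit_means)
  if (is.null(colnames(x))) colnames(x) <- paste0("unit_", seq_len(ncol(x)))
  if (nrow(x) < 4) abort("Need at least 4 observations per correlation.")
  rows <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (sd(v) == 0) {
      return(tibble(unit = colnames(x)[j], r = NA_real_, p = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    n = length(v), note = "zero variance; excluded"))
    }
    ct <- correlation_test(v, trait, alternative = "two.sided",
                           conf_level = conf_level)
    tibble(unit = colnames(x)[j], r = ct$r, p = ct$p,
           ci_lower = ct$ci_lower, ci_upper = ct$ci_upper, n = ct$n,
           note = NA_character_)
  })
  testable <- !is.na(rows$p)
  m <- family_size %||% sum(testable)
  if (m < sum(testable)) {
    abort("`family_size` is smaller than the number of testable units.")
  }
  rows$p_holm <- NA_real_
  rows$p_holm[testable] <- holm_correct(rows$p[testable], family_size = m)
  rows[, c("unit", "r", "p", "p_holm", "ci_lower", "ci_upper", "n", "note")]
}

#' Pattern prediction restricted to one region
#'
#' Runs the standard nested cross-validation with PLS on the voxels of a
#' single region, and reports the sign consistency of the final model's
#' weights (fraction of positive voxel weights after retraining on the full
#' provided sample): values near 0.5 mean the direction of the
#' activity-trait association is not consistent across the region's voxels.
#'
#' @param maps [brain_maps()] or matrix, raw (unscaled).
#' @param atlas a `brain_atlas`.
#' @param region region name or id.
#' @param trait numeric outcome.
#' @param spec a [cv_spec()].
#' @param scaling,standardize preprocessing, as elsewhere.
#' @return a list with `cv` (a `cv_result`), `sign_consistency`, and `model`
#'   (the final region-restricted [pattern_model]).
#' @export
region_pattern_predict <- function(maps, atlas, region, trait,
                                   spec = cv_spec(), scaling = "none",
                                   standardize = TRUE) {
  keep <- unit_voxels(atlas, region, "region")
  if (sum(keep) < 2) abort("Region must have at least 2 voxels.")
  xs <- scale_images_submatrix(maps, keep, scaling)
  cv <- fit_nested_cv(xs, trait, "pls", spec, standardize = standardize,
                      warn_constant = FALSE)
  hyper <- best_hyper(cv)
  xfin <- xs
  vstats <- NULL
  if (standardize) {
    vstats <- voxel_stats(xfin)
    xfin <- apply_voxel_stats(xfin, vstats)
  }
  fit <- single_fit(xfin, trait, "pls", hyper)
  list(cv = cv,
       sign_consistency = mean(fit$beta > 0),
       model = new_pattern_model("pls", hyper, fit, scaling, vstats))
}

# Image-wise scaling computed on the full map, then restricted to a voxel
# subset: region-restricted models still remove the person-wise offset of the
# whole image, not of the region alone.
scale_images_submatrix <- function(maps, keep, scaling) {
  xs <- map_matrix(scale_images(map_matrix(maps), scaling))
  xs[, keep, drop = FALSE]
}

#' Best-region discovery with split-half confirmation
#'
#' Splits the sample into two halves stratified on the trait, picks the unit
#' with the strongest absolute correlation in the first half, and tests that
#' unit's correlation in the second half. Because selection and confirmation
#' use disjoint halves, the confirmatory test keeps its nominal error rate no
#' matter how many units were screened.
#'
#' @param unit_means observations-by-units matrix.
#' @param trait numeric outcome.
#' @param seed seed of the stratified half split.
#' @return a one-row tibble: `unit`, `r_select`, `r_test`, `p_test`, `n_test`.
#' @export
best_region_splithalf <- function(unit_means, trait, seed = 1) {
  x <- as.matrix(unit_means)
  if (ncol(x) < 2) abort("Need at least 2 units to select among.")
  if (nrow(x) < 8) abort("Need at least 8 observations.")
  if (is.null(colnames(x))) colnames(x) <- paste0("unit_", seq_len(ncol(x)))
  if (nrow(x) >= 10) {
    sp <- stratified_split(trait, holdout_fraction = 0.5, seed = seed)
    h1 <- sp$train; h2 <- sp$holdout
  } else {
    # boundary samples: alternate assignment along the sorted trait
    o <- with_seed(seed, order(trait, runif(length(trait))))
    h1 <- o[seq_along(o) %% 2L == 1L]
    h2 <- o[seq_along(o) %% 2L == 0L]
  }
  r1 <- suppressWarnings(cor(x[h1, , drop = FALSE], trait[h1]))[, 1]
  r1[is.na(r1)] <- 0
  j <- which.max(abs(r1))
  ct <- correlation_test(x[h2, j], trait[h2], alternative = "two.sided")
  tibble(unit = colnames(x)[j], r_select = r1[j],
         r_test = ct$r, p_test = ct$p, n_test = ct$n)
}

#' Network-level models of a trait
#'
#' Three models of increasing flexibility on the seven network averages:
#' per-network correlations with Holm correction over the declared family
#' (`"univariate"`), a linear combination via multiple regression
#' (`"multiple_regression"`), and random forest regression evaluated on
#' out-of-bag samples with a permutation test of the OOB correlation
#' (`"random_forest_oob"`).
#'
#' @param network_means observations-by-networks matrix.
#' @param trait numeric outcome.
#' @param model which model to fit.
#' @param family_size Holm family for the univariate model (defaults to the
#'   number of networks).
#' @param n_perm permutations for the forest test.
#' @param num_trees forest size.
#' @param seed RNG seed (forest and permutations).
#' @return univariate: the [region_trait_correlations()] tibble; regression:
#'   a list with the `lm` fit, `r_squared`, and overall F-test `p`; forest:
#'   a list with `r_oob`, `p`, and the null distribution.
#' @export
network_models <- function(network_means, trait,
                           model = c("univariate", "multiple_regression",
                                     "random_forest_oob"),
                           family_size = NULL, n_perm = 1000,
                           num_trees = 500, seed = 1) {
  model <- match.arg(model)
  x <- as.matrix(network_means)
  if (is.null(colnames(x))) colnames(x) <- paste0("network_", seq_len(ncol(x)))
  if (model == "univariate") {
    fam <- family_size %||% ncol(x)
    if (fam < ncol(x)) abort("Declared family smaller than network count.")
    return(region_trait_correlations(x, trait, family_size = fam))
  }
  df <- as.data.frame(x)
  df$.y <- trait
  if (model == "multiple_regression") {
    fit <- lm(.y ~ ., data = df)
    sm <- summary(fit)
    fp <- unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE))
    return(list(fit = fit, r_squared = sm$r.squared, p = fp))
  }
  if (nrow(x) <= 20) abort("Random forest model needs n > 20.")
  oob_r <- function(y, s) {
    rf <- ranger::ranger(x = x, y = y, num.trees = num_trees, seed = s,
                         verbose = FALSE)
    safe_cor(rf$predictions, y, warn_constant = FALSE)
  }
  robs <- oob_r(trait, seed)
  null_r <- vapply(seq_len(n_perm), function(b) {
    yb <- with_seed(child_seed(seed, b), sample(trait))
    oob_r(yb, child_seed(seed, b, 1L))
  }, numeric(1))
  list(r_oob = robs, p = (1 + sum(null_r >= robs)) / (1 + n_perm),
       null = null_r, n_perm = n_perm)
}

#' Expression of a neural signature in each map
#'
#' The scalar expression of a signature in an observation's map is the dot
#' product of the signature's voxel weights with the map's voxel values.
#'
#' @param maps [brain_maps()] or matrix.
#' @param sig a `signature_map` (from [generate_signature()] or
#'   [read_signature()]) or a bare numeric weight vector.
#' @return numeric vector, one expression score per observation.
#' @export
signature_expression <- function(maps, sig) {
  w <- if (inherits(sig, "signature_map")) sig$weights else as.numeric(sig)
  x <- map_matrix(maps)
  if (length(w) != ncol(x)) {
    abort(sprintf("Signature has %d weights but maps have %d voxels.",
                  length(w), ncol(x)))
  }
  if (any(!is.finite(w))) abort("Signature weights must be finite.")
  drop(x %*% w)
}

#' Spatial similarity of two weight maps
#'
#' Pearson correlation of two voxel weight vectors over voxels.
#'
#' @param a,b aligned numeric weight vectors (or `signature_map`s) of length
#'   >= 3.
#' @return the correlation.
#' @export
spatial_similarity <- function(a, b) {
  wa <- if (inherits(a, "signature_map")) a$weights else as.numeric(a)
  wb <- if (inherits(b, "signature_map")) b$weights else as.numeric(b)
  if (length(wa) != length(wb)) abort("Weight vectors are not aligned.")
  if (length(wa) < 3) abort("Need at least 3 voxels.")
  if (sd(wa) == 0 || sd(wb) == 0) {
    abort("Constant weight vector: spatial correlation undefined.")
  }
  cor(wa, wb)
}
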