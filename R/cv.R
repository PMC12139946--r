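#' Specification of the repeated nested cross-validation scheme
#'
#' The default is the 2x5x5 scheme: two repeats for stability, five outer
#' folds for model evaluation, five inner folds for hyperparameter tuning.
#' Performance is always the Pearson correlation of pooled out-of-fold
#' predictions with the outcome, per repeat.
#'
#' @param outer_folds,inner_folds,repeats fold structure (all >= 2, except
#'   `inner_folds` which may be 0 to disable tuning when the grid has one
#'   point).
#' @param seed RNG seed governing every fold assignment.
#' @param grids optional named list of hyperparameter grids per algorithm,
#'   overriding [default_grid()].
#' @return an object of class `cv_spec`.
#' @export
cv_spec <- function(outer_folds = 5, inner_folds = 5, repeats = 2, seed = 1,
                    grids = NULL) {
  if (outer_folds < 2) abort("`outer_folds` must be >= 2.")
  if (repeats < 1) abort("`repeats` must be >= 1.")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats),
                 seed = as.integer(seed), grids = grids),
            class = "cv_spec")
}

make_folds <- function(n, k, seed) {
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

safe_cor <- function(pred, obs, warn_constant = TRUE) {
  if (sd(pred) == 0 || sd(obs) == 0 || anyNA(pred)) {
    if (warn_constant) warn("Constant predictions in a fold; recording r = 0.")
    return(0)
  }
  cor(pred, obs)
}

#' Stratified training / hold-out split
#'
#' Sets aside a hold-out sample whose outcome distribution matches the
#' training sample, by quantile-bin stratification: observations are binned on
#' the outcome and the requested fraction is sampled within each bin, so split
#' sizes can differ by one or two observations from the nominal fraction due
#' to per-bin rounding.
#'
#' @param trait numeric outcome vector.
#' @param holdout_fraction fraction of observations to set aside, in (0, 1).
#' @param seed RNG seed; identical seeds give identical splits.
#' @param n_bins number of quantile bins.
#' @return a list with integer index vectors `train` and `holdout`.
#' @export
stratified_split <- function(trait, holdout_fraction = 0.25, seed = 1,
                             n_bins = 5) {
  n <- length(trait)
  if (n < 10) abort("Need at least 10 observations to split.")
  if (!is_number(holdout_fraction) || holdout_fraction <= 0 ||
      holdout_fraction >= 1) {
    abort("`holdout_fraction` must be in (0, 1).")
  }
  br <- unique(quantile(trait, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE))
  bins <- if (length(br) > 2) {
    cut(trait, breaks = br, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, n)
  }
  holdout <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), bins), function(idx) {
      take <- round(length(idx) * holdout_fraction)
      if (take == 0) return(integer())
      sample(idx, take)
    }), use.names = FALSE)
  })
  holdout <- sort(holdout)
  list(train = setdiff(seq_len(n), holdout), holdout = holdout)
}

#' Repeated nested cross-validation of a whole-brain model
#'
#' Runs the repeated nested scheme of `spec`: within each outer training fold,
#' inner folds select the hyperparameter by the Pearson correlation of pooled
#' inner out-of-fold predictions (ties broken toward the simpler model); the
#' selected model is refit on the outer training fold and predicts the outer
#' test fold. Voxel-wise standardization statistics are computed inside each
#' training fold only, so no test information leaks into preprocessing.
#'
#' @param x [brain_maps()] or matrix (observations by voxels), already
#'   image-wise scaled as desired.
#' @param y numeric outcome, one value per observation.
#' @param algorithm `"pls"`, `"pcr"`, `"svr"`, or `"pcarf"`.
#' @param spec a [cv_spec()].
#' @param standardize voxel-standardize inside folds (default TRUE).
#' @param groups optional grouping vector (e.g. subject ids); observations
#'   sharing a group are always assigned to the same fold.
#' @param warn_constant warn when a fold produces constant predictions
#'   (recorded as r = 0 either way).
#' @return an object of class `cv_result`: fold-wise correlations (
#'   `repeats * outer_folds` of them), pooled out-of-fold predictions per
#'   repeat, the overall correlation per repeat and their mean, and the chosen
#'   hyperparameters per outer fold.
#' @export
fit_nested_cv <- function(x, y, algorithm = "pls", spec = cv_spec(),
                          standardize = TRUE, groups = NULL,
                          warn_constant = TRUE) {
  xm <- map_matrix(x)
  y <- as.numeric(y)
  n <- nrow(xm)
  if (length(y) != n) abort("`y` must have one value per observation.")
  algorithm <- canonical_algorithm(algorithm)

  if (is.null(groups)) {
    units <- seq_len(n)
    unit_of_obs <- seq_len(n)
  } else {
    units <- unique(groups)
    unit_of_obs <- match(groups, units)
  }

  grid <- spec$grids[[algorithm]] %||% NULL
  folds_tbl <- list()
  preds_tbl <- list()
  r_rep <- numeric(spec$repeats)

  for (rep_i in seq_len(spec$repeats)) {
    unit_fold <- make_folds(length(units), spec$outer_folds,
                            child_seed(spec$seed, rep_i))
    fold_of_obs <- unit_fold[unit_of_obs]
    oof <- rep(NA_real_, n)
    for (k in seq_len(spec$outer_folds)) {
      te <- which(fold_of_obs == k)
      tr <- which(fold_of_obs != k)
      xtr <- xm[tr, , drop = FALSE]
      xte <- xm[te, , drop = FALSE]
      if (standardize) {
        st <- voxel_stats(xtr)
        xtr <- apply_voxel_stats(xtr, st)
        xte <- apply_voxel_stats(xte, st)
      }
      g <- grid %||% default_grid(algorithm, length(tr), ncol(xtr))
      chosen <- g[1]
      if (length(g) > 1L && spec$inner_folds >= 2L) {
        tr_units <- unique(unit_of_obs[tr])
        iu_fold <- make_folds(length(tr_units), spec$inner_folds,
                              child_seed(spec$seed, rep_i, k))
        ifold <- iu_fold[match(unit_of_obs[tr], tr_units)]
        inner_pred <- matrix(NA_real_, length(tr), length(g))
        for (j in seq_len(spec$inner_folds)) {
          ite <- which(ifold == j)
          itr <- which(ifold != j)
          if (!length(ite) || length(itr) < 3L) next
          xitr <- xtr[itr, , drop = FALSE]
          xite <- xtr[ite, , drop = FALSE]
          if (standardize) {
            sti <- voxel_stats(xitr)
            xitr <- apply_voxel_stats(xitr, sti)
            xite <- apply_voxel_stats(xite, sti)
          }
          inner_pred[ite, ] <- path_fit_predict(
            xitr, y[tr][itr], xite, algorithm, g,
            seed = child_seed(spec$seed, rep_i, k, j))
        }
        ok <- complete.cases(inner_pred)
        inner_r <- apply(inner_pred[ok, , drop = FALSE], 2, function(p) {
          if (sd(p) == 0) -Inf else cor(p, y[tr][ok])
        })
        chosen <- g[which.max(inner_r)]   # first max: simpler model wins ties
      }
      fit <- single_fit(xtr, y[tr], algorithm,
                        if (is.na(chosen)) NA_real_ else chosen,
                        seed = child_seed(spec$seed, rep_i, k, 99L))
      pred <- fit$predict(xte)
      oof[te] <- pred
      folds_tbl[[length(folds_tbl) + 1L]] <- tibble(
        rep = rep_i, fold = k, r = safe_cor(pred, y[te], warn_constant),
        hyper = if (is.na(chosen)) NA_real_ else chosen,
        n_test = length(te))
    }
    r_rep[rep_i] <- safe_cor(oof, y, warn_constant)
    preds_tbl[[rep_i]] <- tibble(rep = rep_i, index = seq_len(n),
                                 observed = y, predicted = oof)
  }

  structure(
    list(folds = dplyr::bind_rows(folds_tbl),
         predictions = dplyr::bind_rows(preds_tbl),
         r_repeat = r_rep,
         r_mean = mean(r_rep),
         algorithm = algorithm,
         spec = spec),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s, %d repeats x %d folds>\n", x$algorithm,
              x$spec$repeats, x$spec$outer_folds))
  cat(sprintf("  r per repeat: %s; mean r = %.3f\n",
              paste(sprintf("%.3f", x$r_repeat), collapse = ", "), x$r_mean))
  if (!is.null(x$perm_p)) cat(sprintf("  permutation p = %.4f\n", x$perm_p))
  invisible(x)
}

#' Most frequently selected hyperparameter of a nested CV run
#' @param cv a [fit_nested_cv()] result.
#' @return the modal chosen hyperparameter value.
#' @export
best_hyper <- function(cv) {
  h <- cv$folds$hyper
  if (all(is.na(h))) return(NA_real_)
  tab <- sort(table(h), decreasing = TRUE)
  as.numeric(names(tab)[1])
}

#' Permutation test of a cross-validated correlation
#'
#' Re-runs the full nested cross-validation under permutations of the outcome
#' and compares the observed mean cross-validated correlation against the null
#' distribution; `p = (1 + #(null >= observed)) / (1 + n_perm)`, one-tailed,
#' since only positive correlations indicate successful prediction.
#'
#' @inheritParams fit_nested_cv
#' @param n_perm number of permutations (>= 99).
#' @param observed optionally a precomputed [fit_nested_cv()] result for the
#'   unpermuted outcome.
#' @return a list of class `perm_test` with `p`, `observed` (mean r), and
#'   `null` (the permutation distribution).
#' @export
permutation_test_cv <- function(x, y, algorithm = "pls", spec = cv_spec(),
                                n_perm = 1000, standardize = TRUE,
                                observed = NULL) {
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  xm <- map_matrix(x)
  obs <- observed %||% fit_nested_cv(xm, y, algorithm, spec,
                                     standardize = standardize,
                                     warn_constant = FALSE)
  null_r <- vapply(seq_len(n_perm), function(b) {
    yb <- with_seed(child_seed(spec$seed, 7919L, b), sample(y))
    fit_nested_cv(xm, yb, algorithm, spec, standardize = standardize,
                  warn_constant = FALSE)$r_mean
  }, numeric(1))
  structure(list(p = (1 + sum(null_r >= obs$r_mean)) / (1 + n_perm),
                 observed = obs$r_mean, null = null_r, n_perm = n_perm),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test: observed r = %.3f, p = %.4f (%d permutations)>\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

new_pattern_model <- function(algorithm, hyper, fit, scaling, vstats,
                              trait = NA_character_, coords = NULL) {
  structure(
    list(algorithm = algorithm, hyper = hyper,
         beta = fit$beta, intercept = fit$intercept,
         fit = if (is.null(fit$beta)) fit else NULL,
         scaling = scaling, voxel_stats = vstats, trait = trait,
         coords = coords),
    class = "pattern_model"
  )
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("<pattern_model: %s (hyper = %s), trait '%s'>\n", x$algorithm,
              format(x$hyper), x$trait))
  cat(sprintf("  preprocessing: image scaling '%s', voxel standardization %s\n",
              x$scaling, if (is.null(x$voxel_stats)) "off" else "on"))
  invisible(x)
}

#' Apply a trained pattern model to new maps
#'
#' Applies the model's stored preprocessing (image-wise scaling mode, then the
#' training-sample voxel statistics) before predicting, so a model can never
#' silently be applied to differently-preprocessed maps. Input maps must be
#' raw (unscaled); a `brain_maps` input whose provenance already records
#' scaling raises an error.
#'
#' @param object a `pattern_model`.
#' @param newdata [brain_maps()] or matrix of raw maps.
#' @param ... unused.
#' @return numeric vector of predictions / pattern expressions.
#' @export
predict.pattern_model <- function(object, newdata, ...) {
  if (inherits(newdata, "brain_maps") &&
      any(startsWith(newdata$provenance, "scale:"))) {
    abort(paste0("Maps are already image-wise scaled; pattern models apply ",
                 "their own stored preprocessing to raw maps."))
  }
  xm <- map_matrix(scale_images(newdata, object$scaling))
  p_expect <- length(object$beta %||% object$voxel_stats$mean)
  if (p_expect > 0 && ncol(xm) != p_expect) {
    abort("Voxel space of `newdata` does not match the trained model.")
  }
  if (!is.null(object$voxel_stats)) {
    xm <- apply_voxel_stats(xm, object$voxel_stats)
  }
  if (!is.null(object$beta)) {
    drop(xm %*% object$beta) + object$intercept
  } else {
    pcarf_predict(object$fit, xm)
  }
}

#' Train a final model on the training sample and evaluate on hold-out
#'
#' Refits the selected algorithm/hyperparameter on the entire training sample
#' (with preprocessing statistics from the training sample only), predicts the
#' untouched hold-out sample, and scores the predictions with a one-sided
#' correlation test, Fisher-z confidence interval, and one-sided stretched-beta
#' Bayes factor.
#'
#' @param x_train,x_holdout raw maps ([brain_maps()] or matrices) for the two
#'   samples; the function guards against the hold-out being identical to the
#'   training sample.
#' @param y_train,y_holdout outcome vectors.
#' @param algorithm,hyper selected algorithm and hyperparameter (e.g. from
#'   [best_hyper()]).
#' @param scaling image-wise scaling mode applied identically to both samples.
#' @param standardize voxel-standardize on training statistics.
#' @param kappa prior scale of the Bayes factor.
#' @param alternative sidedness of the confirmatory test.
#' @return a list of class `holdout_eval` with `inference` (one-row tibble:
#'   r, n, p, CI, BF10, kappa), `model` (the trained [pattern_model]), and
#'   `predictions`.
#' @export
train_final_and_evaluate <- function(x_train, y_train, x_holdout, y_holdout,
                                     algorithm = "pls", hyper = NULL,
                                     scaling = "none", standardize = TRUE,
                                     kappa = 1 / 3,
                                     alternative = "greater") {
  xtr_raw <- map_matrix(x_train)
  xho_raw <- map_matrix(x_holdout)
  if (ncol(xtr_raw) != ncol(xho_raw)) {
    abort("Training and hold-out maps must share one voxel space.")
  }
  if (nrow(xtr_raw) == nrow(xho_raw) &&
      isTRUE(all.equal(xtr_raw, xho_raw, tolerance = 0))) {
    abort("Hold-out sample is identical to the training sample.")
  }
  algorithm <- canonical_algorithm(algorithm)
  xtr <- scale_images(xtr_raw, scaling)
  xho <- scale_images(xho_raw, scaling)
  vstats <- NULL
  if (standardize) {
    vstats <- voxel_stats(xtr)
    xtr <- apply_voxel_stats(xtr, vstats)
    xho <- apply_voxel_stats(xho, vstats)
  }
  if (is.null(hyper) || (length(hyper) == 1 && is.na(hyper))) {
    hyper <- if (algorithm == "pcarf") NA_real_
             else default_grid(algorithm, nrow(xtr), ncol(xtr))[1]
  }
  fit <- single_fit(xtr, y_train, algorithm, hyper, seed = 1L)
  pred <- fit$predict(xho)
  inf <- correlation_test(pred, y_holdout, alternative = alternative)
  inf$bf10 <- if (abs(inf$r) < 1) {
    correlation_bf(inf$r, inf$n, alternative = alternative, kappa = kappa)
  } else {
    NA_real_
  }
  inf$kappa <- kappa
  coords <- if (inherits(x_train, "brain_maps")) x_train$coords
  model <- new_pattern_model(algorithm, hyper, fit, scaling, vstats,
                             coords = coords)
  structure(list(inference = inf, model = model,
                 predictions = tibble(observed = y_holdout, predicted = pred)),
            class = "holdout_eval")
}

#' @export
print.holdout_eval <- function(x, ...) {
  i <- x$inference
  cat(sprintf(
    "<holdout_eval: r(%d) = %.3f, p = %.4f (%s), BF10 = %.2f, 95%% CI [%.2f, %.2f]>\n",
    i$n - 2, i$r, i$p, i$alternative, i$bf10, i$ci_lower, i$ci_upper))
  invisible(x)
}

# 6-connectivity connected components on integer grid coordinates.
grid_components <- function(coords) {
  dims <- apply(coords, 2, max) + 2L
  key <- function(cc) {
    1 + cc[, 1] + dims[1] * (cc[, 2] + dims[2] * cc[, 3])
  }
  lookup <- new.env(hash = TRUE, size = nrow(coords))
  ks <- key(coords)
  for (i in seq_len(nrow(coords))) {
    assign(as.character(ks[i]), i, envir = lookup)
  }
  comp <- integer(nrow(coords))
  cur <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(nrow(coords))) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- sweep(offs, 2L, as.numeric(coords[v, ]), "+")
      nb <- nb[nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0, , drop = FALSE]
      if (!nrow(nb)) next
      for (kk in key(nb)) {
        j <- mget(as.character(kk), envir = lookup,
                  ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' Bootstrap thresholding of pattern weights
#'
#' Resamples training observations with replacement, refits the linear model
#' at the chosen hyperparameter, and derives per-voxel two-sided p-values
#' from the bootstrap distribution of each weight (percentile sign p-value
#' with add-one smoothing; the `mean / SD` bootstrap z is also reported).
#' Voxels are thresholded at `alpha` (optionally FDR-adjusted), then
#' connected components (6-connectivity on the 3-D grid) smaller than
#' `min_cluster` voxels are removed.
#'
#' @param x raw maps ([brain_maps()] with grid coordinates, or a matrix plus
#'   `coords`).
#' @param y training outcome.
#' @param algorithm,hyper a linear algorithm (`pls`, `pcr`, `svr`) and its
#'   hyperparameter.
#' @param scaling,standardize preprocessing, as in
#'   [train_final_and_evaluate()].
#' @param alpha voxel-wise threshold level.
#' @param min_cluster minimum cluster extent in voxels.
#' @param n_boot number of bootstrap resamples (>= 500).
#' @param method `"uncorrected"` or `"fdr"`.
#' @param coords voxel coordinates when `x` is a matrix.
#' @param seed RNG seed for resampling.
#' @return a list of class `thresholded_pattern`: `weights` (mean bootstrap
#'   weights, zeroed outside surviving voxels), `surviving` (logical),
#'   `z`, `p`, and a `clusters` tibble.
#' @export
threshold_pattern_weights <- function(x, y, algorithm = "pls", hyper = NULL,
                                      scaling = "none", standardize = TRUE,
                                      alpha = 0.05, min_cluster = 50,
                                      n_boot = 500,
                                      method = c("uncorrected", "fdr"),
                                      coords = NULL, seed = 1) {
  method <- match.arg(method)
  algorithm <- canonical_algorithm(algorithm)
  if (algorithm == "pcarf") {
    abort("Weight thresholding requires a linear algorithm (pls/pcr/svr).")
  }
  if (n_boot < 500) abort("`n_boot` must be at least 500.")
  coords <- coords %||% if (inherits(x, "brain_maps")) x$coords
  if (is.null(coords)) abort("Voxel `coords` are required for clustering.")
  xm <- map_matrix(scale_images(x, scaling))
  n <- nrow(xm); p <- ncol(xm)
  hyper <- hyper %||% default_grid(algorithm, n, p)[1]
  W <- matrix(0, n_boot, p)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- xm[idx, , drop = FALSE]
      if (standardize) xb <- apply_voxel_stats(xb, voxel_stats(xb))
      W[b, ] <- single_fit(xb, y[idx], algorithm, hyper)$beta
    }
  })
  mw <- colMeans(W)
  sw <- sqrt(pmax(colMeans(W^2) - mw^2, 0) * n_boot / (n_boot - 1))
  z <- ifelse(sw > 0, mw / sw, 0)
  # two-sided percentile-bootstrap sign p-value (add-one smoothed). A normal
  # reference on mean/SD is anticonservative for these estimators (the
  # bootstrap SD of a direction-selective weight underestimates its sampling
  # SD), so p is read off the bootstrap distribution itself; its resolution
  # is bounded below by 2 / (n_boot + 1).
  n_nonpos <- colSums(W <= 0)
  pv <- pmin(1, 2 * (1 + pmin(n_nonpos, n_boot - n_nonpos)) / (n_boot + 1))
  thr <- if (method == "fdr") p.adjust(pv, "BH") < alpha else pv < alpha
  surviving <- thr
  clusters <- tibble(cluster = integer(), n_voxels = integer())
  if (any(thr)) {
    comp <- grid_components(coords[thr, , drop = FALSE])
    sizes <- tabulate(comp)
    keep_comp <- which(sizes >= min_cluster)
    surv_sub <- comp %in% keep_comp
    surviving[which(thr)] <- surv_sub
    if (length(keep_comp)) {
      clusters <- tibble(cluster = seq_along(keep_comp),
                         n_voxels = as.integer(sizes[keep_comp]))
    }
  }
  weights <- ifelse(surviving, mw, 0)
  structure(list(weights = weights, surviving = surviving, z = z, p = pv,
                 clusters = clusters, alpha = alpha,
                 min_cluster = min_cluster, method = method),
            class = "thresholded_pattern")
}

#' Virtual lesion analysis of a trained model
#'
#' For each region or network, removes its voxels from both samples, retrains
#' the final model on the reduced training space (or, optionally, only zeroes
#' the removed weights without retraining), re-evaluates on the hold-out
#' sample, and reports the change in hold-out correlation relative to the full
#' model.
#'
#' @inheritParams train_final_and_evaluate
#' @param atlas a `brain_atlas` aligned with the maps.
#' @param level `"region"` or `"network"`.
#' @param units units to lesion (default: all at `level`).
#' @param retrain retrain on the reduced voxel space (TRUE, default) or only
#'   zero the removed voxels' weights (FALSE).
#' @return a tibble of class `lesion_result` with `unit`, `r_lesioned`,
#'   `delta_r`, and the full-model `r_full` as an attribute.
#' @export
lesion_analysis <- function(x_train, y_train, x_holdout, y_holdout, atlas,
                            level = c("network", "region"), units = NULL,
                            algorithm = "pls", hyper = NULL,
                            scaling = "none", standardize = TRUE,
                            retrain = TRUE) {
  level <- match.arg(level)
  full <- train_final_and_evaluate(x_train, y_train, x_holdout, y_holdout,
                                   algorithm, hyper, scaling, standardize)
  r_full <- full$inference$r
  nm <- switch(level, region = atlas$region_names,
               network = atlas$network_names)
  units <- units %||% nm
  xtr <- map_matrix(x_train); xho <- map_matrix(x_holdout)
  rows <- purrr::map_dfr(units, function(u) {
    keep <- !unit_voxels(atlas, u, level)
    if (retrain) {
      ev <- train_final_and_evaluate(
        xtr[, keep, drop = FALSE], y_train,
        xho[, keep, drop = FALSE], y_holdout,
        algorithm, hyper, scaling, standardize)
      r_les <- ev$inference$r
    } else {
      beta <- full$model$beta
      if (is.null(beta)) abort("`retrain = FALSE` requires a linear model.")
      xs <- scale_images(xho, full$model$scaling)
      if (!is.null(full$model$voxel_stats)) {
        xs <- apply_voxel_stats(xs, full$model$voxel_stats)
      }
      b2 <- beta; b2[!keep] <- 0
      r_les <- safe_cor(drop(xs %*% b2), y_holdout, warn_constant = FALSE)
    }
    tibble(unit = if (is.character(u)) u else nm[u],
           r_lesioned = r_les, delta_r = r_les - r_full)
  })
  attr(rows, "r_full") <- r_full
  class(rows) <- c("lesion_result", class(rows))
  rows
}
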