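# broom-style tidiers for the fitted objects.

#' Tidy a nested cross-validation result
#' @param x a `cv_result`.
#' @param ... unused.
#' @return the fold-level tibble (`rep`, `fold`, `r`, `hyper`, `n_test`).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row summary of a nested cross-validation result
#' @param x a `cv_result`.
#' @param ... unused.
#' @return tibble with `algorithm`, `r_mean`, per-repeat correlations,
#'   fold-r SD, and the modal hyperparameter.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    algorithm = x$algorithm,
    r_mean = x$r_mean,
    r_repeat_min = min(x$r_repeat),
    r_repeat_max = max(x$r_repeat),
    sd_fold_r = sd(x$folds$r),
    hyper = best_hyper(x),
    n_folds = nrow(x$folds)
  )
}

#' Tidy a trained pattern model into a voxel-weight table
#' @param x a `pattern_model` (linear algorithms only).
#' @param ... unused.
#' @return tibble with `voxel`, `weight`, and grid coordinates when known.
#' @method tidy pattern_model
#' @export
tidy.pattern_model <- function(x, ...) {
  if (is.null(x$beta)) {
    abort("Nonlinear pattern models have no voxel weight vector to tidy.")
  }
  out <- tibble(voxel = seq_along(x$beta), weight = x$beta)
  if (!is.null(x$coords)) {
    out$x <- x$coords[, 1]; out$y <- x$coords[, 2]; out$z <- x$coords[, 3]
  }
  out
}

#' Tidy a permutation test
#' @param x a `perm_test`.
#' @param ... unused.
#' @return tibble of the null distribution, one row per permutation.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(permutation = seq_along(x$null), r_null = x$null)
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(observed_r = x$observed, p = x$p, n_perm = x$n_perm)
}

#' @method glance holdout_eval
#' @export
glance.holdout_eval <- function(x, ...) x$inference

#' @method tidy holdout_eval
#' @export
tidy.holdout_eval <- function(x, ...) x$predictions

#' @method glance reliability_result
#' @export
glance.reliability_result <- function(x, ...) {
  tibble(r_half = x$r_half, r_corrected = x$r_corrected,
         n_subjects = x$n_subjects, scheme = x$scheme)
}

#' @method tidy reliability_result
#' @export
tidy.reliability_result <- function(x, ...) x$expressions

#' @method tidy state_decoding
#' @export
tidy.state_decoding <- function(x, ...) x$per_subject

#' @method glance state_decoding
#' @export
glance.state_decoding <- function(x, ...) {
  tibble(mean_r = x$mean_r, sd_r = x$sd_r, n_subjects = nrow(x$per_subject))
}
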