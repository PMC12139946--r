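# Psychometrics of a trained pattern: split-half reliability of its
# person-wise expression, convergent/discriminant validity of its
# cross-validated predictions, and within-person decoding of dynamic state
# ratings.

#' Split-half reliability of person-wise pattern expression
#'
#' Splits every subject's trials into two halves (odd/even trial index by
#' default, for reproducibility; random halves behind a seed), rebuilds the
#' condition contrast map from each half, computes the pattern expression of
#' both half-contrasts, correlates the two expressions across subjects, and
#' applies the Spearman-Brown correction to project to full-length
#' reliability.
#'
#' @param trial_maps [brain_maps()] with `subject`, `trial`, `condition`
#'   metadata.
#' @param pattern a [pattern_model] (its stored preprocessing is applied) or a
#'   bare weight vector (applied to raw half-contrasts).
#' @param scheme `"oddeven"` or `"random"`.
#' @param seed seed for the random scheme.
#' @return a list of class `reliability_result` with `r_half`, `r_corrected`,
#'   `n_subjects`, and the per-subject half expressions.
#' @export
split_half_reliability <- function(trial_maps, pattern,
                                   scheme = c("oddeven", "random"), seed = 1) {
  scheme <- match.arg(scheme)
  obs <- trial_maps$obs
  if (is.null(obs) || !all(c("subject", "trial", "condition") %in% names(obs))) {
    abort("`trial_maps` needs subject/trial/condition metadata.")
  }
  half <- switch(scheme,
                 oddeven = obs$trial %% 2L + 1L,
                 random = with_seed(seed, {
                   unlist(lapply(split(seq_len(nrow(obs)), obs$subject),
                                 function(i) sample(rep(1:2, length.out = length(i)))),
                          use.names = FALSE)[order(order(obs$subject))]
                 }))
  subjects <- unique(obs$subject)
  x <- map_matrix(trial_maps)
  expr_half <- function(h) {
    ok_subj <- character()
    rows <- matrix(NA_real_, length(subjects), ncol(x))
    for (i in seq_along(subjects)) {
      sel <- obs$subject == subjects[i] & half == h
      neg <- sel & obs$condition == "negative"
      neu <- sel & obs$condition == "neutral"
      if (sum(neg) < 1 || sum(neu) < 1) next
      rows[i, ] <- colMeans(x[neg, , drop = FALSE]) -
        colMeans(x[neu, , drop = FALSE])
      ok_subj <- c(ok_subj, as.character(subjects[i]))
    }
    rows
  }
  h1 <- expr_half(1L); h2 <- expr_half(2L)
  ok <- complete.cases(h1) & complete.cases(h2)
  if (sum(!ok)) {
    warn(sprintf("%d subject(s) lacked both conditions in a half; excluded.",
                 sum(!ok)))
  }
  score <- function(m) {
    if (inherits(pattern, "pattern_model")) {
      predict(pattern, m[ok, , drop = FALSE])
    } else {
      signature_expression(m[ok, , drop = FALSE], pattern)
    }
  }
  e1 <- score(h1); e2 <- score(h2)
  r_half <- cor(e1, e2)
  structure(
    list(r_half = r_half, r_corrected = spearman_brown(r_half),
         n_subjects = sum(ok), scheme = scheme,
         expressions = tibble(subject = subjects[ok], half1 = e1, half2 = e2)),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "<reliability_result: split-half r = %.3f, Spearman-Brown corrected r = %.3f (%d subjects, %s halves)>\n",
    x$r_half, x$r_corrected, x$n_subjects, x$scheme))
  invisible(x)
}

#' Convergent and discriminant validity by leave-one-out prediction
#'
#' Produces leave-one-out cross-validated predictions of the target trait
#' (hyperparameter chosen once by k-fold inner CV on the full sample), then
#' correlates the predictions with the target (reference performance), with
#' convergent traits (expected positive), and with discriminant traits
#' (expected near zero).
#'
#' @param maps raw maps, one row per subject.
#' @param traits trait tibble (one row per subject; see
#'   [generate_cohort()]).
#' @param target name of the predicted trait column.
#' @param convergent,discriminant character vectors of trait columns.
#' @param algorithm learning algorithm.
#' @param scaling,standardize preprocessing.
#' @param inner_folds folds of the single hyperparameter selection.
#' @param seed RNG seed for the selection folds.
#' @return a tibble of class `validity_table` with `trait`, `role`, `r`.
#' @export
loo_validity <- function(maps, traits, target,
                         convergent = character(),
                         discriminant = character(),
                         algorithm = "pls", scaling = "none",
                         standardize = TRUE, inner_folds = 5, seed = 1) {
  all_tr <- c(target, convergent, discriminant)
  missing_tr <- setdiff(all_tr, names(traits))
  if (length(missing_tr)) {
    abort(paste0("Traits not in the table: ",
                 paste(missing_tr, collapse = ", ")))
  }
  y <- traits[[target]]
  if (anyNA(traits[all_tr])) abort("Traits must be complete for all subjects.")
  x <- map_matrix(scale_images(map_matrix(maps), scaling))
  n <- nrow(x)
  if (n < 10) abort("Need at least 10 subjects for leave-one-out validity.")
  sel <- fit_nested_cv(x, y, algorithm,
                       cv_spec(outer_folds = inner_folds, inner_folds = inner_folds,
                               repeats = 1, seed = seed),
                       standardize = standardize, warn_constant = FALSE)
  hyper <- best_hyper(sel)
  pred <- vapply(seq_len(n), function(i) {
    xtr <- x[-i, , drop = FALSE]
    if (standardize) {
      st <- voxel_stats(xtr)
      xtr <- apply_voxel_stats(xtr, st)
      xte <- apply_voxel_stats(x[i, , drop = FALSE], st)
    } else {
      xte <- x[i, , drop = FALSE]
    }
    single_fit(xtr, y[-i], algorithm, hyper,
               seed = child_seed(seed, i))$predict(xte)
  }, numeric(1))
  role <- c("target", rep("convergent", length(convergent)),
            rep("discriminant", length(discriminant)))
  out <- tibble(
    trait = all_tr, role = role,
    r = unname(vapply(all_tr, function(tr) cor(pred, traits[[tr]]),
                      numeric(1)))
  )
  attr(out, "predictions") <- pred
  attr(out, "hyper") <- hyper
  class(out) <- c("validity_table", class(out))
  out
}

#' Within-person decoding of state ratings from trial maps
#'
#' Trains a pattern on trial-wise maps and ratings of training-fold subjects
#' (folds split by subject, so all trials of a person share a fold and no
#' person contributes to both sides), then, for each held-out subject,
#' correlates predicted with actual ratings across that subject's trials.
#' Reports the mean and SD of these within-person correlations. Because a
#' per-person constant offset is shared by all of a subject's trials, it
#' cannot contribute to within-person correlations when image-wise centering
#' is applied -- which is why state decoding survives the offsets that poison
#' between-person prediction.
#'
#' @param trial_maps [brain_maps()] with `subject` metadata.
#' @param ratings numeric vector of per-trial ratings (defaults to the
#'   `rating` metadata column).
#' @param algorithm learning algorithm.
#' @param spec a [cv_spec()]; outer folds group subjects.
#' @param scaling,standardize preprocessing (centering by default, matching
#'   the trait-pattern procedure).
#' @return a list of class `state_decoding` with `per_subject` (tibble), and
#'   `mean_r`, `sd_r` across subjects.
#' @export
within_person_decode <- function(trial_maps, ratings = NULL,
                                 algorithm = "pls", spec = cv_spec(),
                                 scaling = "center", standardize = TRUE) {
  obs <- trial_maps$obs
  if (is.null(obs) || !"subject" %in% names(obs)) {
    abort("`trial_maps` needs subject metadata.")
  }
  ratings <- ratings %||% obs$rating
  if (is.null(ratings)) abort("No ratings supplied or found in metadata.")
  tr_per_subj <- table(obs$subject)
  if (any(tr_per_subj < 5)) abort("Need at least 5 rated trials per subject.")
  x <- scale_images(map_matrix(trial_maps), scaling)
  cv <- fit_nested_cv(x, as.numeric(ratings), algorithm, spec,
                      standardize = standardize, groups = obs$subject,
                      warn_constant = FALSE)
  pred <- cv$predictions
  per_subj <- pred |>
    dplyr::mutate(subject = rep(obs$subject, times = spec$repeats)) |>
    dplyr::group_by(.data$rep, .data$subject) |>
    dplyr::summarise(
      r = if (sd(.data$observed) == 0) NA_real_
          else cor(.data$predicted, .data$observed),
      n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(r = mean(.data$r), n_trials = .data$n_trials[1],
                     .groups = "drop")
  if (anyNA(per_subj$r)) {
    warn(sprintf("%d subject(s) with constant ratings excluded from the average.",
                 sum(is.na(per_subj$r))))
  }
  structure(
    list(per_subject = per_subj,
         mean_r = mean(per_subj$r, na.rm = TRUE),
         sd_r = sd(per_subj$r, na.rm = TRUE),
         between_person_cv = cv),
    class = "state_decoding"
  )
}

#' @export
print.state_decoding <- function(x, ...) {
  cat(sprintf(
    "<state_decoding: mean within-person r = %.3f (SD = %.3f) over %d subjects>\n",
    x$mean_r, x$sd_r, nrow(x$per_subject)))
  invisible(x)
}
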