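# Multiverse of design choices: staged factorial grids, sweep execution,
# random-forest design-factor importance, and mixed-model variance
# decomposition.

NEUROTICISM_OUTCOMES <- c("neuroticism", "depression", "anxiety",
                          "vulnerability", "anger", "impulsiveness",
                          "self_consciousness")
STAGE3_EXTRA_OUTCOMES <- c("negative_affect", "positive_affect",
                           "trait_anxiety", "depression_severity",
                           "neuroticism_other", "neuroticism_combined",
                           "task_ratings")

#' Build the staged factorial grid of design points
#'
#' Stage 1 crosses task (scenes, faces), baseline (control-condition,
#' implicit), and image-wise scaling (none, center, zscore) with outcome fixed
#' to neuroticism, PLS, and the training sample: 12 models. Stage 2 expands
#' the outcome to the seven neuroticism scores (domain + six facets) and the
#' algorithm to PLS/PCR/SVR: 252 models. Stage 3 expands the outcomes to 14
#' affective traits and the algorithm-sample combinations to seven (PLS, PCR,
#' SVR on both the training and the full sample, plus PCA-random-forest on
#' the training sample): 1,176 models under the reference configuration; the
#' exact crossing is explicit configuration, and the builder reports whatever
#' its factor lists imply.
#'
#' @param stage 1, 2, or 3.
#' @param available_outcomes optional character vector restricting outcomes to
#'   those present in a trait table.
#' @param overrides named list replacing factor level sets (`task`,
#'   `baseline`, `scaling`, `outcome`, `algorithm`, `sample`).
#' @return a tibble of design points (one row each) with a `model_id` column.
#' @export
build_design_grid <- function(stage = 1, available_outcomes = NULL,
                              overrides = list()) {
  if (!stage %in% 1:3) abort("`stage` must be 1, 2, or 3.")
  levels <- list(
    task = c("scenes", "faces"),
    baseline = c("control", "implicit"),
    scaling = c("none", "center", "zscore"),
    outcome = switch(as.character(stage),
                     "1" = "neuroticism",
                     "2" = NEUROTICISM_OUTCOMES,
                     "3" = c(NEUROTICISM_OUTCOMES, STAGE3_EXTRA_OUTCOMES)),
    algorithm = switch(as.character(stage),
                       "1" = "pls",
                       "2" = c("pls", "pcr", "svr"),
                       "3" = c("pls", "pcr", "svr", "pcarf")),
    sample = if (stage == 3) c("training", "full") else "training"
  )
  bad <- setdiff(names(overrides), names(levels))
  if (length(bad)) {
    abort(paste0("Unknown design factor(s): ", paste(bad, collapse = ", ")))
  }
  levels[names(overrides)] <- overrides
  known <- list(task = c("scenes", "faces"),
                baseline = c("control", "implicit"),
                scaling = c("none", "center", "zscore"),
                algorithm = ALGORITHMS,
                sample = c("training", "full"))
  for (f in names(known)) {
    unk <- setdiff(levels[[f]], known[[f]])
    if (length(unk)) {
      abort(sprintf("Unknown level(s) for %s: %s", f,
                    paste(unk, collapse = ", ")))
    }
  }
  if (!is.null(available_outcomes)) {
    levels$outcome <- intersect(levels$outcome, available_outcomes)
    if (!length(levels$outcome)) abort("No requested outcome is available.")
  }
  grid <- tidyr::expand_grid(
    task = levels$task, baseline = levels$baseline, scaling = levels$scaling,
    outcome = levels$outcome, algorithm = levels$algorithm,
    sample = levels$sample)
  if (stage == 3 && is.null(overrides$algorithm) &&
      is.null(overrides$sample)) {
    # reference restriction: the nonlinear algorithm is only run on the
    # training sample, giving the 7 algorithm-sample combinations
    grid <- dplyr::filter(grid, !(.data$algorithm == "pcarf" &
                                    .data$sample == "full"))
  }
  dplyr::mutate(grid, model_id = dplyr::row_number(), stage = stage,
                .before = 1)
}

#' Execute every design point of a multiverse grid
#'
#' Runs the shared nested cross-validation for each design point on the
#' matching cohort maps and outcome, recording one row per (design point x
#' repeat x outer fold) with its fold correlation. Every design point uses
#' the same `cv_spec` seed policy, so identical design points give identical
#' results and the sweep is invariant to execution order. A failure in one
#' design point is caught, logged, and marked in the table without aborting
#' the sweep.
#'
#' @param grid a [build_design_grid()] tibble.
#' @param cohort a [generate_cohort()] result.
#' @param spec a [cv_spec()].
#' @param split optional list with `train` indices (from
#'   [stratified_split()]); computed from the cohort's configuration when a
#'   grid point needs the training sample and none is given.
#' @param progress print one line per design point.
#' @return a tibble of class `multiverse_table` with columns of the grid plus
#'   `rep`, `fold`, `r`, `failed`.
#' @export
run_multiverse <- function(grid, cohort, spec = cv_spec(), split = NULL,
                           progress = FALSE) {
  if (!nrow(grid)) abort("Empty design grid.")
  if (is.null(split) && "training" %in% grid$sample) {
    split <- stratified_split(cohort$traits$neuroticism,
                              cohort$config$holdout_fraction,
                              seed = cohort$config$seed)
  }
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    res <- tryCatch({
      maps <- cohort_maps(cohort, g$task, g$baseline, g$scaling)
      idx <- if (g$sample == "training") split$train
             else seq_len(nrow(cohort$traits))
      y <- cohort$traits[[g$outcome]][idx]
      cv <- fit_nested_cv(map_matrix(maps)[idx, , drop = FALSE], y,
                          g$algorithm, spec, warn_constant = FALSE)
      dplyr::bind_cols(g[rep(1, nrow(cv$folds)), ],
                       cv$folds[, c("rep", "fold", "r")],
                       tibble(failed = FALSE))
    }, error = function(e) {
      inform(sprintf("Design point %d failed: %s", g$model_id,
                     conditionMessage(e)))
      dplyr::bind_cols(g, tibble(rep = NA_integer_, fold = NA_integer_,
                                 r = NA_real_, failed = TRUE))
    })
    if (progress) {
      inform(sprintf("[%d/%d] %s/%s/%s %s %s (%s): mean r = %.3f",
                     i, nrow(grid), g$task, g$baseline, g$scaling, g$outcome,
                     g$algorithm, g$sample, mean(res$r)))
    }
    res
  })
  class(rows) <- c("multiverse_table", class(rows))
  rows
}

#' Per-model summary of a multiverse table
#' @param table a [run_multiverse()] result.
#' @return a tibble with one row per design point and its mean fold
#'   correlation `r_mean`.
#' @export
summarise_multiverse <- function(table) {
  table |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("model_id", "stage", "task", "baseline", "scaling", "outcome",
        "algorithm", "sample")))) |>
    dplyr::summarise(r_mean = mean(.data$r), .groups = "drop")
}

multiverse_factors <- function(table) {
  cand <- c("task", "baseline", "scaling", "outcome", "algorithm", "sample")
  fac <- intersect(cand, names(table))
  fac[vapply(fac, function(f) length(unique(table[[f]])) >= 1L, logical(1))]
}

#' Random-forest importance of design factors
#'
#' Regresses the fold-level correlations on the design factors with a random
#' forest of bagged trees and reports permutation-based variable importance,
#' expressed as the increase in out-of-bag root-mean-squared error when the
#' factor is permuted. Descriptive only: fold rows of one model are dependent,
#' so no p-values are attached.
#'
#' @param table a [run_multiverse()] result.
#' @param num_trees forest size (default 1,000 bagged trees).
#' @param seed RNG seed.
#' @return a tibble of class `design_importance` with `factor`,
#'   `importance_rmse` (sorted descending), plus attributes `r_squared` (OOB
#'   variance explained) and `rmse_oob`.
#' @export
design_importance <- function(table, num_trees = 1000, seed = 1) {
  tbl <- dplyr::filter(table, !.data$failed)
  fac <- multiverse_factors(tbl)
  if (!length(fac)) abort("No design factors in the table.")
  df <- as.data.frame(lapply(tbl[fac], factor))
  df$.r <- tbl$r
  varying <- names(df)[vapply(df, function(v) length(unique(v)) > 1L,
                              logical(1))]
  varying <- setdiff(varying, ".r")
  rf <- ranger::ranger(
    dependent.variable.name = ".r",
    data = df[, c(varying, ".r"), drop = FALSE],
    num.trees = num_trees, mtry = length(varying),  # bagged trees
    importance = "permutation", seed = seed,
    respect.unordered.factors = "partition", verbose = FALSE)
  mse <- rf$prediction.error
  imp_mse <- setNames(rep(0, length(fac)), fac)
  imp_mse[names(rf$variable.importance)] <- rf$variable.importance
  out <- tibble(
    factor = fac,
    importance_rmse = sqrt(pmax(mse + imp_mse, 0)) - sqrt(mse)
  ) |> dplyr::arrange(dplyr::desc(.data$importance_rmse))
  attr(out, "r_squared") <- rf$r.squared
  attr(out, "rmse_oob") <- sqrt(mse)
  class(out) <- c("design_importance", class(out))
  out
}

#' Variance decomposition of fold correlations over design factors
#'
#' Fits a crossed random-intercept model (REML) with one random effect per
#' design factor and reports the standard deviation of fold correlations
#' attributable to each factor and to the residual. Negative variance
#' estimates are truncated at zero by the fitting procedure itself. Aliased
#' (perfectly confounded) factors are rejected with an error naming the pair.
#'
#' @param table a [run_multiverse()] result.
#' @return a tibble of class `variance_decomposition` with `component`, `sd`,
#'   `variance`, `proportion`.
#' @export
variance_decomposition <- function(table) {
  tbl <- dplyr::filter(table, !.data$failed)
  fac <- multiverse_factors(tbl)
  fac <- fac[vapply(fac, function(f) length(unique(tbl[[f]])) >= 2L,
                    logical(1))]
  if (!length(fac)) abort("Need at least one factor with 2+ levels.")
  # confounding check: two factors whose level partitions coincide
  if (length(fac) > 1) {
    for (i in seq_len(length(fac) - 1)) {
      for (j in seq(i + 1, length(fac))) {
        ta <- table(tbl[[fac[i]]], tbl[[fac[j]]])
        if (all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)) {
          abort(sprintf("Design factors '%s' and '%s' are perfectly confounded.",
                        fac[i], fac[j]))
        }
      }
    }
  }
  if (sd(tbl$r) == 0) {
    out <- tibble(component = c(fac, "residual"), sd = 0, variance = 0,
                  proportion = NA_real_)
    class(out) <- c("variance_decomposition", class(out))
    return(out)
  }
  fml <- as.formula(paste("r ~ 1 +",
                          paste(sprintf("(1 | %s)", fac), collapse = " + ")))
  fit <- lme4::lmer(fml, data = tbl, REML = TRUE,
                    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                check.nobs.vs.nRE = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- tibble(
    component = ifelse(vc$grp == "Residual", "residual", vc$grp),
    sd = vc$sdcor,
    variance = vc$vcov
  )
  out$proportion <- out$variance / sum(out$variance)
  ord <- match(c(fac, "residual"), out$component)
  out <- out[ord[!is.na(ord)], ]
  class(out) <- c("variance_decomposition", class(out))
  out
}

#' Export a multiverse table for interactive exploration
#'
#' Writes the tidy fold-level table to CSV and a self-contained HTML page
#' with a sortable, text-filterable table of per-model mean correlations --
#' the static stand-in for a hosted exploration app.
#'
#' @param table a [run_multiverse()] result.
#' @param csv_path,html_path output paths (either may be NULL to skip).
#' @return invisibly, the per-model summary tibble.
#' @export
export_multiverse <- function(table, csv_path = NULL, html_path = NULL) {
  summ <- summarise_multiverse(table)
  if (!is.null(csv_path)) write.csv(table, csv_path, row.names = FALSE)
  if (!is.null(html_path)) {
    cols <- setdiff(names(summ), "stage")
    head_html <- paste0("<th>", cols, "</th>", collapse = "")
    rows_html <- apply(summ[cols], 1, function(rr) {
      paste0("<tr>", paste0("<td>", vapply(rr, function(v) {
        if (is.numeric(v)) sprintf("%.4f", v) else as.character(v)
      }, character(1)), "</td>", collapse = ""), "</tr>")
    })
    html <- c(
      "<!DOCTYPE html><html><head><meta charset='utf-8'>",
      "<title>Multiverse results</title>",
      "<style>body{font-family:sans-serif}table{border-collapse:collapse}",
      "td,th{border:1px solid #999;padding:2px 8px}</style></head><body>",
      "<h1>Multiverse of brain-trait models</h1>",
      "<p>One row per design point; r is the mean cross-validated fold",
      "correlation.</p>",
      "<input id='f' placeholder='filter rows...' oninput=\"",
      "var q=this.value.toLowerCase();",
      "document.querySelectorAll('tbody tr').forEach(function(tr){",
      "tr.style.display=tr.textContent.toLowerCase().includes(q)?'':'none';});\">",
      paste0("<table><thead><tr>", head_html, "</tr></thead><tbody>"),
      rows_html,
      "</tbody></table></body></html>")
    writeLines(html, html_path)
  }
  invisible(summ)
}
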