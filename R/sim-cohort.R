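#' Generate a synthetic cohort with known ground truth
#'
#' Simulates a cohort of subjects performing a scenes-style affective task
#' (negative and neutral picture trials with 1-5 Likert state ratings) plus a
#' null "faces" task, at the trial-map level. The generative model for a trial
#' map is
#'
#' `X[i,t,v] = g0_i + I(neg) * (g_i + h_i[net(v)] + beta_trait * b_i * w_trait_v)
#'            + beta_state * a_it * w_state_v + e_itv`
#'
#' where `g0_i` is a per-person baseline offset (cancels in condition
#' contrasts), `g_i` a per-person global reactivity offset (survives in
#' contrasts and drives high between-network correlations), `h_i` per-network
#' reactivity offsets, `b_i` the latent brain-coupled trait (the
#' facet-specific part of vulnerability to stress), `w_trait` a sparse
#' region-structured trait pattern, `a_it` the latent state intensity that
#' also drives the self-reported rating, and `w_state` a distributed,
#' predominantly positive state pattern. Condition contrast maps are computed
#' from the trial maps exactly as an analysis would (mean negative minus mean
#' neutral), so the trait signal, reactivity offsets, and state signal survive
#' into them while the baseline offset cancels; implicit-baseline contrasts
#' keep the baseline offset. Questionnaire scores are reliability-attenuated
#' transforms of the latent factors.
#'
#' @param config a [sim_config()].
#' @return an object of class `cohort`: list with `config`, `atlas`,
#'   `trial_maps` ([brain_maps()] with subject/trial/condition/rating
#'   metadata), `contrasts` (named list of subject-level [brain_maps()]:
#'   `scenes_control`, `scenes_implicit`, `faces_control`, `faces_implicit`),
#'   `ratings`, `traits` (tibble, one row per subject), and `truth`
#'   (ground-truth patterns and latent scores).
#' @export
generate_cohort <- function(config) {
  config <- as_sim_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  atlas <- generate_atlas(cfg)
  V <- prod(cfg$grid_shape)
  n <- cfg$n_subjects
  K <- cfg$n_networks
  net_of_voxel <- atlas$network[atlas$region]

  # --- ground-truth spatial patterns -------------------------------------
  # state pattern: smooth (region-structured), predominantly positive
  region_eff <- rnorm(cfg$n_regions)
  w_state <- 0.8 + region_eff[atlas$region] + rnorm(V, sd = 0.5)
  w_state <- w_state / sqrt(sum(w_state^2))

  # trait pattern: region-constant random signs inside the support networks,
  # centered over its support so it is immune to global/network offsets
  support_nets <- vapply(cfg$trait_support$networks, resolve_unit,
                         integer(1), atlas = atlas, level = "network")
  cand <- which(atlas$network %in% support_nets)
  sizes <- tabulate(atlas$region, nbins = cfg$n_regions)[cand]
  target <- max(1L, round(cfg$trait_support$fraction * V))
  keep <- which(cumsum(sizes) <= max(target, sizes[1]))
  support_regions <- cand[keep]
  support <- atlas$region %in% support_regions
  signs <- sample(c(-1, 1), length(support_regions), replace = TRUE)
  w_trait <- numeric(V)
  w_trait[support] <- signs[match(atlas$region[support], support_regions)]
  w_trait[support] <- w_trait[support] - mean(w_trait[support])
  nrm <- sqrt(sum(w_trait^2))
  if (nrm == 0) {
    # all support signs identical after centering (single region): fall back
    w_trait[support] <- 1
    w_trait <- w_trait / sqrt(sum(w_trait^2))
  } else {
    w_trait <- w_trait / nrm
  }

  # --- latent person variables -------------------------------------------
  lam <- cfg$facet_structure$domain_loading
  d <- rnorm(n)
  u <- matrix(rnorm(n * 6), n, 6)
  facets <- lam * d + sqrt(1 - lam^2) * u
  facet_names <- c("depression", "anxiety", "vulnerability", "anger",
                   "impulsiveness", "self_consciousness")
  colnames(facets) <- facet_names
  b <- u[, 3]                               # brain-coupled: vulnerability-specific
  # the domain score reflects the shared factor itself; facet-specific
  # variance (including the brain-coupled part) enters only the facet scores
  domain_latent <- d

  g0 <- rnorm(n, sd = cfg$sigma_baseline)
  g <- rnorm(n, sd = cfg$sigma_global)
  h <- matrix(rnorm(n * K, sd = cfg$sigma_network), n, K)
  psi <- cfg$reactivity_trait_cor
  s <- cfg$sigma_reactivity * (psi * b + sqrt(1 - psi^2) * rnorm(n))

  # --- trial-level task data ---------------------------------------------
  nneg <- cfg$n_trials_neg; nneu <- cfg$n_trials_neu
  ntr <- nneg + nneu
  # counterbalanced ABBA ordering so any odd/even trial split contains both
  # conditions; leftover trials of the larger condition go to the end
  npair <- min(nneg, nneu)
  pairs <- unlist(lapply(seq_len(npair), function(i) {
    if (i %% 2L == 1L) c("negative", "neutral") else c("neutral", "negative")
  }))
  cond_seq <- c(pairs,
                rep("negative", nneg - npair), rep("neutral", nneu - npair))
  subject <- rep(seq_len(n), each = ntr)
  condition <- rep(cond_seq, times = n)
  trial <- rep(seq_len(ntr), times = n)
  is_neg <- condition == "negative"

  mu_cond <- ifelse(is_neg, 1, -1)
  a <- mu_cond + s[subject] * is_neg + rnorm(n * ntr, sd = cfg$sigma_state)
  rating <- pmin(5, pmax(1, round(3 + a + rnorm(n * ntr,
                                                sd = cfg$rating_noise))))

  X <- matrix(rnorm(n * ntr * V, sd = cfg$sigma_noise), n * ntr, V)
  X <- X + tcrossprod(cfg$beta_state * a, w_state)
  X <- X + g0[subject]
  # per-subject negative-condition response pattern
  P <- h[, net_of_voxel, drop = FALSE] + g +
    tcrossprod(cfg$beta_trait * b, w_trait)
  X[is_neg, ] <- X[is_neg, ] + P[subject[is_neg], , drop = FALSE]

  obs <- tibble(subject = subject, trial = trial, condition = condition,
                rating = as.integer(rating))
  trial_maps <- brain_maps(X, coords = atlas$coords, obs = obs,
                           grid = atlas$grid)

  m_neg <- rowsum(X[is_neg, , drop = FALSE], subject[is_neg]) / nneg
  m_neu <- rowsum(X[!is_neg, , drop = FALSE], subject[!is_neg]) / nneu
  subj_obs <- tibble(subject = seq_len(n))
  mk_maps <- function(m) brain_maps(unname(m), coords = atlas$coords,
                                    obs = subj_obs, grid = atlas$grid)

  # faces task: same offset structure, no trait or state signal
  sigma_c <- cfg$sigma_noise * sqrt(1 / nneg + 1 / nneu)
  gf0 <- rnorm(n, sd = cfg$sigma_baseline)
  gf <- rnorm(n, sd = cfg$sigma_global)
  hf <- matrix(rnorm(n * K, sd = cfg$sigma_network), n, K)
  F_ctrl <- matrix(rnorm(n * V, sd = sigma_c), n, V) +
    hf[, net_of_voxel, drop = FALSE] + gf

  contrasts <- list(
    scenes_control = mk_maps(m_neg - m_neu),
    scenes_implicit = mk_maps(m_neg),
    faces_control = mk_maps(F_ctrl),
    faces_implicit = mk_maps(F_ctrl + gf0)
  )

  # --- questionnaire scores ----------------------------------------------
  rel <- cfg$reliability
  atten <- function(latent, r) {
    sqrt(r) * latent + sqrt(1 - r) * rnorm(length(latent))
  }
  mix <- function(loads, vars) {
    resv <- 1 - sum(loads^2)
    stopifnot(resv >= 0)
    drop(vars %*% loads) + sqrt(resv) * rnorm(n)
  }
  cb <- cfg$facet_structure$convergent_loading
  na_lat <- mix(c(cb, 0.45), cbind(b, d))
  pa_lat <- mix(-0.25, cbind(d))
  ex_lat <- mix(-0.30, cbind(d))
  stai_lat <- mix(c(0.65, 0.20), cbind(d, b))
  bdi_lat <- mix(c(0.55, 0.25), cbind(d, u[, 1]))

  rel_dom <- min(1, rel + 0.1)
  neuro <- atten(domain_latent, rel_dom)
  neuro_other <- atten(domain_latent, rel * 0.75)
  rt_tbl <- tibble(subject = subject, condition = condition,
                   rating = as.numeric(rating))
  mean_by <- function(keep) {
    rowsum(rt_tbl$rating[keep], rt_tbl$subject[keep])[, 1] /
      tabulate(rt_tbl$subject[keep], nbins = n)
  }
  task_ratings <- mean_by(is_neg) - mean_by(!is_neg)

  traits <- tibble(subject = seq_len(n), neuroticism = neuro)
  for (j in seq_along(facet_names)) {
    traits[[facet_names[j]]] <- atten(facets[, j], rel)
  }
  traits$negative_affect <- atten(na_lat, rel)
  traits$positive_affect <- atten(pa_lat, rel)
  traits$trait_anxiety <- atten(stai_lat, rel)
  traits$depression_severity <- atten(bdi_lat, rel)
  traits$neuroticism_other <- neuro_other
  traits$neuroticism_combined <-
    as.numeric(scale(neuro + neuro_other))
  traits$task_ratings <- task_ratings
  traits$extraversion <- atten(ex_lat, rel)

  truth <- list(
    w_state = w_state,
    w_trait = w_trait,
    support_regions = support_regions,
    support_networks = support_nets,
    latent = tibble(subject = seq_len(n), domain = d, brain_trait = b,
                    reactivity = s, global = g, baseline = g0)
  )

  structure(
    list(config = cfg, atlas = atlas, trial_maps = trial_maps,
         contrasts = contrasts,
         ratings = obs, traits = traits, truth = truth),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort: %d subjects, %d trials/subject, %d voxels, %d regions/%d networks>\n",
    x$config$n_subjects, x$config$n_trials_neg + x$config$n_trials_neu,
    prod(x$config$grid_shape), x$config$n_regions, x$config$n_networks))
  cat("  contrasts:", paste(names(x$contrasts), collapse = ", "), "\n")
  cat("  traits:", paste(setdiff(names(x$traits), "subject"),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Fetch a contrast-map variant from a cohort
#'
#' Convenience accessor used by the multiverse sweep: selects the task /
#' baseline combination and applies the requested image-wise scaling.
#'
#' @param cohort a [generate_cohort()] result.
#' @param task `"scenes"` or `"faces"`.
#' @param baseline `"control"` (condition contrast) or `"implicit"`.
#' @param scaling image-wise scaling mode passed to [scale_images()].
#' @return a [brain_maps()] object, one row per subject.
#' @export
cohort_maps <- function(cohort, task = c("scenes", "faces"),
                        baseline = c("control", "implicit"),
                        scaling = c("none", "center", "zscore")) {
  task <- match.arg(task)
  baseline <- match.arg(baseline)
  scaling <- match.arg(scaling)
  maps <- cohort$contrasts[[paste(task, baseline, sep = "_")]]
  scale_images(maps, scaling)
}

#' Generate a synthetic neural signature
#'
#' Produces a unit-norm voxel weight vector standing in for a published
#' affective signature, optionally constructed to have an exact spatial
#' (Pearson over voxels) correlation with the cohort's true state pattern.
#'
#' @param cohort a [generate_cohort()] result (defines the voxel space and the
#'   true state pattern).
#' @param kind one of `"negative-affect"`, `"fear"`, `"sadness"`, `"anger"`,
#'   `"fear2"`; only used as the signature's name and to vary the default
#'   seed.
#' @param spatial_r target spatial correlation with the true state pattern,
#'   in `[-1, 1]`.
#' @param seed RNG seed; defaults to a kind-specific child of the cohort seed.
#' @return an object of class `signature_map` with fields `name` and
#'   `weights` (unit norm).
#' @export
generate_signature <- function(cohort,
                               kind = c("negative-affect", "fear", "sadness",
                                        "anger", "fear2"),
                               spatial_r = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is_number(spatial_r) || spatial_r < -1 || spatial_r > 1) {
    abort("`spatial_r` must be in [-1, 1].")
  }
  ws <- cohort$truth$w_state
  V <- length(ws)
  seed <- seed %||% child_seed(cohort$config$seed, match(kind, c(
    "negative-affect", "fear", "sadness", "anger", "fear2")))
  w <- with_seed(seed, {
    cs <- ws - mean(ws)
    z <- rnorm(V)
    z <- z - mean(z)
    z <- z - cs * sum(z * cs) / sum(cs^2)
    z <- z * sqrt(sum(cs^2) / sum(z^2))
    raw <- spatial_r * cs + sqrt(1 - spatial_r^2) * z + mean(ws)
    raw / sqrt(sum(raw^2))
  })
  structure(list(name = kind, weights = w), class = "signature_map")
}

#' @export
print.signature_map <- function(x, ...) {
  cat(sprintf("<signature_map '%s': %d voxels, norm %.3f>\n",
              x$name, length(x$weights), sqrt(sum(x$weights^2))))
  invisible(x)
}
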