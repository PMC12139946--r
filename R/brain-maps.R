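#' Observation-by-voxel brain map container
#'
#' `brain_maps` is the pipeline currency: a dense matrix of observations
#' (subjects or trials) by voxels, together with the integer grid coordinate of
#' every voxel, per-observation metadata, and a provenance record of the
#' transforms already applied. All modelling functions accept either a
#' `brain_maps` object or a plain numeric matrix.
#'
#' @param data numeric matrix, observations in rows, voxels in columns.
#' @param coords integer matrix with one row per voxel and three columns
#'   (0-based grid indices). Defaults to a dummy 1-D layout, which is enough
#'   for everything except cluster-extent thresholding and NIfTI export.
#' @param obs optional tibble/data.frame of per-observation metadata (e.g.
#'   `subject`, `condition`, `trial`), one row per observation.
#' @param grid integer(3), the full grid dimensions the coordinates live on.
#' @param provenance character vector of transforms already applied.
#'
#' @return an object of class `brain_maps`.
#' @export
brain_maps <- function(data, coords = NULL, obs = NULL, grid = NULL,
                       provenance = character()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  v <- ncol(data)
  if (is.null(coords)) {
    coords <- cbind(x = seq_len(v) - 1L, y = 0L, z = 0L)
    grid <- grid %||% c(v, 1L, 1L)
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (nrow(coords) != v) {
    abort("`coords` must have one row per voxel (column of `data`).")
  }
  if (ncol(coords) != 3L) abort("`coords` must have three columns.")
  if (is.null(grid)) grid <- apply(coords, 2, max) + 1L
  if (!is.null(obs)) {
    obs <- as_tibble(obs)
    if (nrow(obs) != nrow(data)) {
      abort("`obs` must have one row per observation (row of `data`).")
    }
  }
  structure(
    list(data = data, coords = coords, grid = as.integer(grid), obs = obs,
         provenance = provenance),
    class = "brain_maps"
  )
}

#' @export
print.brain_maps <- function(x, ...) {
  cat(sprintf("<brain_maps: %d observations x %d voxels on a %s grid>\n",
              nrow(x$data), ncol(x$data), paste(x$grid, collapse = "x")))
  if (!is.null(x$obs)) {
    cat("  obs columns:", paste(names(x$obs), collapse = ", "), "\n")
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.brain_maps <- function(x) dim(x$data)

#' Extract the data matrix from maps or pass a matrix through
#' @param x a `brain_maps` object or numeric matrix.
#' @return numeric matrix, observations by voxels.
#' @export
map_matrix <- function(x) {
  if (inherits(x, "brain_maps")) x$data else as.matrix(x)
}

n_voxels <- function(x) ncol(map_matrix(x))
n_obs <- function(x) nrow(map_matrix(x))

# Rebuild a brain_maps object with new data and/or a voxel subset.
replace_data <- function(maps, data, keep_voxels = NULL, note = NULL) {
  if (!inherits(maps, "brain_maps")) return(data)
  coords <- maps$coords
  if (!is.null(keep_voxels)) coords <- coords[keep_voxels, , drop = FALSE]
  prov <- maps$provenance
  if (!is.null(note)) prov <- c(prov, note)
  brain_maps(data, coords = coords, obs = maps$obs, grid = maps$grid,
             provenance = prov)
}

# Subset observations (rows), keeping metadata aligned.
subset_obs <- function(maps, idx) {
  if (!inherits(maps, "brain_maps")) return(maps[idx, , drop = FALSE])
  obs <- if (!is.null(maps$obs)) maps$obs[idx, , drop = FALSE]
  brain_maps(maps$data[idx, , drop = FALSE], coords = maps$coords,
             obs = obs, grid = maps$grid, provenance = maps$provenance)
}

#' Restrict maps to an inclusion mask
#'
#' Drops all voxels (columns) outside a logical mask, keeping the coordinate
#' table aligned. Used both for the initial gray-matter mask and for
#' re-evaluating a model under a stricter ("sparse") mask.
#'
#' @param maps a [brain_maps()] object or matrix.
#' @param mask logical vector, one entry per current voxel.
#' @return maps restricted to `mask == TRUE`.
#' @export
apply_gray_mask <- function(maps, mask) {
  mask <- as.logical(mask)
  if (length(mask) != n_voxels(maps)) {
    abort(sprintf("`mask` has length %d but maps have %d voxels.",
                  length(mask), n_voxels(maps)))
  }
  if (anyNA(mask)) abort("`mask` must not contain NA.")
  if (!any(mask)) abort("`mask` excludes every voxel.")
  x <- map_matrix(maps)[, mask, drop = FALSE]
  if (inherits(maps, "brain_maps")) {
    replace_data(maps, x, keep_voxels = mask,
                 note = sprintf("mask:%d/%d", sum(mask), length(mask)))
  } else {
    x
  }
}

#' Image-wise scaling of each observation's map
#'
#' Normalizes every observation (row) by its own statistics across voxels:
#' `"center"` subtracts the row mean, `"zscore"` additionally divides by the
#' row standard deviation (sample, n-1 convention), `"none"` is the identity.
#' Centering removes any per-person constant activity offset exactly, which is
#' the mechanism by which image-wise scaling choices change between-person
#' prediction.
#'
#' @param maps a [brain_maps()] object or matrix.
#' @param mode one of `"none"`, `"center"`, `"zscore"`.
#' @return maps with every row rescaled; provenance gains a `scale:` entry.
#' @export
scale_images <- function(maps, mode = c("none", "center", "zscore")) {
  mode <- match.arg(mode)
  x <- map_matrix(maps)
  if (inherits(maps, "brain_maps") &&
      any(startsWith(maps$provenance, "scale:"))) {
    abort("These maps are already image-wise scaled (see provenance).")
  }
  if (mode != "none") {
    if (ncol(x) < 2L && mode == "zscore") {
      abort("zscore scaling needs at least 2 voxels per observation.")
    }
    mu <- rowMeans(x)
    x <- x - mu
    if (mode == "zscore") {
      s <- sqrt(rowSums(x^2) / (ncol(x) - 1L))
      bad <- which(s <= 0 | !is.finite(s))
      if (length(bad)) {
        abort(sprintf(
          "zscore scaling: observation(s) %s have zero variance across voxels.",
          paste(head(bad, 5L), collapse = ", ")))
      }
      x <- x / s
    }
  }
  if (inherits(maps, "brain_maps")) {
    replace_data(maps, x, note = paste0("scale:", mode))
  } else {
    x
  }
}

# Column mean/sd statistics on a training matrix (sample sd, n-1).
voxel_stats <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  if (n > 1L) {
    s <- sqrt((colSums(x^2) - n * mu^2) / (n - 1L))
    s[s < 0 | !is.finite(s)] <- 0
  } else {
    s <- rep(0, ncol(x))
  }
  list(mean = mu, sd = s)
}

# Apply train-set voxel statistics: zero-variance voxels are mapped to 0 so the
# voxel space stays aligned across pipeline stages.
apply_voxel_stats <- function(x, stats) {
  s <- stats$sd
  zero <- s <= 0
  s[zero] <- 1
  out <- sweep(x, 2L, stats$mean, "-")
  out <- sweep(out, 2L, s, "/")
  if (any(zero)) out[, zero] <- 0
  out
}

#' Voxel-wise standardization on training-sample statistics
#'
#' z-standardizes every voxel (column) of `apply_to` using the mean and sample
#' standard deviation of that voxel in `train`. Inside cross-validation the
#' statistics must come from the training fold only; this function is that
#' contract made explicit. Zero-variance training voxels are set to 0 (with a
#' warning) rather than dropped, so voxel spaces stay aligned.
#'
#' @param train maps or matrix supplying the statistics.
#' @param apply_to maps or matrix to transform; defaults to `train`.
#' @return `apply_to` transformed; `brain_maps` provenance gains
#'   `standardize:voxel`.
#' @export
standardize_voxels <- function(train, apply_to = train) {
  xtr <- map_matrix(train)
  xap <- map_matrix(apply_to)
  if (ncol(xtr) != ncol(xap)) {
    abort("`train` and `apply_to` must share one voxel space.")
  }
  st <- voxel_stats(xtr)
  if (any(st$sd <= 0)) {
    warn(sprintf("%d zero-variance voxel(s) set to 0 after standardization.",
                 sum(st$sd <= 0)))
  }
  out <- apply_voxel_stats(xap, st)
  if (inherits(apply_to, "brain_maps")) {
    replace_data(apply_to, out, note = "standardize:voxel")
  } else {
    out
  }
}

#' Multivariate outlier detection by Mahalanobis distance
#'
#' Computes each observation's squared Mahalanobis distance to the sample mean
#' under the sample covariance, converts it to a chi-square p-value with `p`
#' degrees of freedom, applies a Holm correction across observations, and flags
#' observations with adjusted p below `alpha` for exclusion. Intended feature
#' set: a low-dimensional summary such as the seven network-average
#' activations, not raw voxels.
#'
#' @param features numeric matrix or data frame, observations by features,
#'   with `nrow > ncol`.
#' @param alpha family-wise error level for exclusion (default 0.05).
#' @return a tibble with columns `observation`, `d2`, `p`, `p_holm`,
#'   `excluded`.
#' @export
detect_outliers <- function(features, alpha = 0.05) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (n <= p) {
    abort(sprintf("Need more observations (%d) than features (%d).", n, p))
  }
  cv <- stats::cov(x)
  d2 <- tryCatch(
    mahalanobis(x, colMeans(x), cv),
    error = function(e) abort(paste0(
      "Covariance is singular; reduce the feature set ",
      "(e.g. use network averages): ", conditionMessage(e)))
  )
  pv <- pchisq(d2, df = p, lower.tail = FALSE)
  ph <- p.adjust(pv, method = "holm")
  tibble(
    observation = seq_len(n),
    d2 = as.numeric(d2),
    p = pv,
    p_holm = ph,
    excluded = ph < alpha
  )
}
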