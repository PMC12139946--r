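# Whole-brain learning algorithms behind the staged model search.
#
# PLS (SIMPLS) and PCR are implemented directly so that one decomposition
# yields the coefficient path over all candidate component counts, which makes
# the inner hyperparameter loop of nested cross-validation a single fit.
# Linear SVR is e1071; the PCA + random forest algorithm is ranger on
# principal-component scores.

ALGORITHMS <- c("pls", "pcr", "svr", "pcarf")

canonical_algorithm <- function(algorithm) {
  key <- tolower(gsub("[^a-z]", "", tolower(algorithm)))
  out <- switch(key,
                pls = "pls", pcr = "pcr", svr = "svr",
                pcarf = "pcarf", rf = "pcarf",
                abort(sprintf("Unknown algorithm '%s'.", algorithm)))
  out
}

#' Default hyperparameter grids
#'
#' Component counts for PLS/PCR are `{1, 2, 5, 10, 20}` capped at half the
#' training-sample size and at the voxel count; SVR uses a linear kernel with
#' cost on a log grid and epsilon fixed at `0.1 * sd(y)`; the PCA + random
#' forest algorithm has no tuned hyperparameter (the component count is fixed
#' at the training-sample size, capped by rank).
#'
#' @param algorithm algorithm id.
#' @param n_train training-sample size.
#' @param p number of voxels/features.
#' @return numeric vector of candidate hyperparameter values (components for
#'   PLS/PCR, cost for SVR), ordered simple to complex.
#' @export
default_grid <- function(algorithm, n_train, p) {
  algorithm <- canonical_algorithm(algorithm)
  switch(algorithm,
         pls = ,
         pcr = {
           cap <- max(1L, min(floor(n_train / 2), p, n_train - 2L))
           sort(unique(pmin(c(1L, 2L, 5L, 10L, 20L), cap)))
         },
         svr = 10^seq(-3, 2),
         pcarf = NA_real_)
}

# SIMPLS for a single response. Returns projection weights so coefficients can
# be formed for any number of components up to ncomp_max.
simpls_fit <- function(x, y, ncomp_max) {
  n <- nrow(x); p <- ncol(x)
  ncomp_max <- min(ncomp_max, n - 1L, p)
  xm <- colMeans(x); ym <- mean(y)
  xc <- x - rep(xm, each = n)
  yc <- y - ym
  s <- crossprod(xc, yc)
  W <- matrix(0, p, ncomp_max)
  V <- matrix(0, p, ncomp_max)
  q <- numeric(ncomp_max)
  a_used <- 0L
  for (a in seq_len(ncomp_max)) {
    w <- s
    t_sc <- xc %*% w
    nt <- sqrt(sum(t_sc^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t_sc <- t_sc / nt
    w <- w / nt
    pa <- crossprod(xc, t_sc)
    q[a] <- sum(yc * t_sc)
    v <- pa
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    V[, a] <- v
    W[, a] <- w
    s <- s - v * sum(v * s)
    a_used <- a
  }
  list(W = W[, seq_len(max(a_used, 1L)), drop = FALSE],
       q = q[seq_len(max(a_used, 1L))],
       xmeans = xm, ymean = ym, ncomp = a_used)
}

simpls_coef <- function(fit, ncomp) {
  k <- min(ncomp, fit$ncomp)
  if (k < 1L) {
    return(list(beta = numeric(length(fit$xmeans)), intercept = fit$ymean))
  }
  beta <- drop(fit$W[, seq_len(k), drop = FALSE] %*% fit$q[seq_len(k)])
  list(beta = beta, intercept = fit$ymean - sum(fit$xmeans * beta))
}

pcr_fit <- function(x, y, ncomp_max) {
  n <- nrow(x); p <- ncol(x)
  ncomp_max <- min(ncomp_max, n - 1L, p)
  xm <- colMeans(x); ym <- mean(y)
  xc <- x - rep(xm, each = n)
  sv <- svd(xc, nu = ncomp_max, nv = ncomp_max)
  d <- sv$d[seq_len(ncomp_max)]
  pos <- d > max(d[1], 0) * 1e-10
  # gamma_k = (u_k' y) / d_k, coefficient path is cumulative in V %*% gamma
  gam <- crossprod(sv$u, y - ym)
  gam <- ifelse(pos, drop(gam) / d, 0)
  list(V = sv$v, gamma = gam, xmeans = xm, ymean = ym,
       ncomp = sum(pos))
}

pcr_coef <- function(fit, ncomp) {
  k <- min(ncomp, length(fit$gamma))
  if (k < 1L) {
    return(list(beta = numeric(length(fit$xmeans)), intercept = fit$ymean))
  }
  beta <- drop(fit$V[, seq_len(k), drop = FALSE] %*% fit$gamma[seq_len(k)])
  list(beta = beta, intercept = fit$ymean - sum(fit$xmeans * beta))
}

svr_fit <- function(x, y, cost, epsilon = NULL) {
  epsilon <- epsilon %||% (0.1 * sd(y))
  if (!is.finite(epsilon) || epsilon <= 0) epsilon <- 0.1
  m <- e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                  cost = cost, epsilon = epsilon, scale = FALSE)
  beta <- drop(crossprod(m$coefs, m$SV))
  full <- numeric(ncol(x))
  sv_idx <- as.integer(colnames(m$SV) %||% seq_along(beta))
  # e1071 keeps all columns for dense input; beta already has length p
  if (length(beta) == ncol(x)) full <- beta else full[sv_idx] <- beta
  list(beta = full, intercept = -m$rho)
}

pcarf_fit <- function(x, y, num_trees = 500, seed = 1) {
  n <- nrow(x); p <- ncol(x)
  ncomp <- min(n, p, n - 1L)   # feature space reduced to the training-sample size
  xm <- colMeans(x)
  xc <- x - rep(xm, each = n)
  sv <- svd(xc, nu = ncomp, nv = ncomp)
  scores <- sv$u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  colnames(scores) <- paste0("pc", seq_len(ncomp))
  df <- as.data.frame(scores)
  df$.y <- y
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, seed = seed,
    respect.unordered.factors = "ignore", verbose = FALSE
  )
  list(rf = rf, rotation = sv$v[, seq_len(ncomp), drop = FALSE],
       xmeans = xm, ncomp = ncomp)
}

pcarf_predict <- function(fit, newx) {
  xc <- newx - rep(fit$xmeans, each = nrow(newx))
  scores <- xc %*% fit$rotation
  colnames(scores) <- paste0("pc", seq_len(ncol(scores)))
  predict(fit$rf, data = as.data.frame(scores))$predictions
}

# Fit on a training set and return a prediction matrix over the whole
# hyperparameter grid (columns follow `grid`). Used by the inner CV loop.
path_fit_predict <- function(xtr, ytr, xte, algorithm, grid, seed = 1) {
  algorithm <- canonical_algorithm(algorithm)
  if (algorithm %in% c("pls", "pcr")) {
    fit <- if (algorithm == "pls") simpls_fit(xtr, ytr, max(grid))
           else pcr_fit(xtr, ytr, max(grid))
    coef_fun <- if (algorithm == "pls") simpls_coef else pcr_coef
    preds <- vapply(grid, function(k) {
      cf <- coef_fun(fit, k)
      drop(xte %*% cf$beta) + cf$intercept
    }, numeric(nrow(xte)))
  } else if (algorithm == "svr") {
    preds <- vapply(grid, function(cost) {
      cf <- svr_fit(xtr, ytr, cost)
      drop(xte %*% cf$beta) + cf$intercept
    }, numeric(nrow(xte)))
  } else {
    fit <- pcarf_fit(xtr, ytr, seed = seed)
    preds <- matrix(pcarf_predict(fit, xte), ncol = 1L)
  }
  matrix(preds, nrow = nrow(xte))
}

# Single fit at a chosen hyperparameter; returns a lightweight model with a
# `$predict(newx)` closure and, for linear algorithms, `beta`/`intercept`.
single_fit <- function(x, y, algorithm, hyper, seed = 1) {
  algorithm <- canonical_algorithm(algorithm)
  if (algorithm == "pls") {
    cf <- simpls_coef(simpls_fit(x, y, hyper), hyper)
  } else if (algorithm == "pcr") {
    cf <- pcr_coef(pcr_fit(x, y, hyper), hyper)
  } else if (algorithm == "svr") {
    cf <- svr_fit(x, y, hyper)
  } else {
    fit <- pcarf_fit(x, y, seed = seed)
    return(list(algorithm = algorithm, hyper = NA_real_, fit = fit,
                beta = NULL, intercept = NULL,
                predict = function(newx) pcarf_predict(fit, newx)))
  }
  force(cf)
  list(algorithm = algorithm, hyper = hyper, beta = cf$beta,
       intercept = cf$intercept,
       predict = function(newx) drop(newx %*% cf$beta) + cf$intercept)
}
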