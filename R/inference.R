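#' Pearson correlation test with Fisher-z confidence interval
#'
#' Computes the Pearson correlation of `x` and `y`, a t-based p-value under the
#' requested alternative, and a two-sided Fisher-z confidence interval
#' (`atanh(r) +/- z / sqrt(n - 3)`, mapped back with `tanh`). The interval is
#' two-sided at `conf_level` regardless of the test's sidedness, matching the
#' convention of reporting one-tailed p-values next to 95% intervals.
#'
#' @param x,y numeric vectors of equal length, `n >= 4`, non-constant.
#' @param alternative `"greater"` (positive correlations mean successful
#'   prediction), `"two.sided"`, or `"less"`.
#' @param conf_level confidence level of the two-sided interval.
#' @return a one-row tibble with `r`, `n`, `statistic`, `p`, `ci_lower`,
#'   `ci_upper`, `conf_level`, `alternative`.
#' @export
correlation_test <- function(x, y,
                             alternative = c("greater", "two.sided", "less"),
                             conf_level = 0.95) {
  alternative <- match.arg(alternative)
  ok <- complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  n <- length(x)
  if (n < 4L) abort("Need at least 4 complete observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Constant input: correlation undefined.")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    tstat <- sign(r) * Inf
    p <- switch(alternative,
                greater = if (r > 0) 0 else 1,
                less = if (r < 0) 0 else 1,
                two.sided = 0)
    ci <- c(r, r)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- switch(alternative,
                greater = pt(tstat, df = n - 2, lower.tail = FALSE),
                less = pt(tstat, df = n - 2),
                two.sided = 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE))
    zcrit <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(atanh(r) + c(-1, 1) * zcrit / sqrt(n - 3))
  }
  tibble(
    r = r, n = n, statistic = tstat, p = p,
    ci_lower = ci[1], ci_upper = ci[2],
    conf_level = conf_level, alternative = alternative
  )
}

# log Gauss hypergeometric 2F1(a, b; c, z) by its power series; valid for
# 0 <= z < 1 with c > 0. Parameters here are small (1/2) and c large (~n), so
# the series converges quickly and every term is positive.
log_2f1 <- function(a, b, cc, z) {
  if (z < 0 || z >= 1) abort("log_2f1 requires 0 <= z < 1.")
  if (z == 0) return(0)
  logz <- log(z)
  lt <- 0; s <- 1
  for (k in 0:20000) {
    lt <- lt + log(a + k) + log(b + k) - log(cc + k) + logz - log(k + 1)
    term <- exp(lt)
    s <- s + term
    if (term < 1e-17 * s) return(log(s))
  }
  abort("log_2f1 series did not converge.")
}

# log of the reduced likelihood of an observed Pearson r given population rho,
# up to a rho-free constant:
#   (1-rho^2)^((n-1)/2) * (1-rho*r)^((3-2n)/2) * 2F1(1/2,1/2; n-1/2; (1+rho*r)/2)
correlation_loglik <- function(rho, r, n) {
  vapply(rho, function(p) {
    (n - 1) / 2 * log1p(-p^2) + (3 - 2 * n) / 2 * log1p(-p * r) +
      log_2f1(0.5, 0.5, n - 0.5, (1 + p * r) / 2)
  }, numeric(1))
}

#' One- and two-sided Bayes factor for a Pearson correlation
#'
#' Bayes factor of the alternative over the null for an observed correlation
#' `r` at sample size `n`, under a stretched-beta prior on the population
#' correlation: `(rho + 1) / 2 ~ Beta(1/kappa, 1/kappa)` on `(-1, 1)`,
#' truncated to positive (or negative) values for one-sided alternatives. The
#' marginal likelihood is obtained by adaptive quadrature of the exact reduced
#' likelihood of `r` given `rho`. `kappa = 1/3` is the conventional "medium"
#' default of correlation Bayes-factor software; `kappa = 1` gives the uniform
#' prior.
#'
#' @param r observed Pearson correlation, `abs(r) < 1`.
#' @param n sample size, `n >= 4`.
#' @param alternative `"greater"`, `"two.sided"`, or `"less"`.
#' @param kappa prior scale in `(0, 1]`.
#' @return the Bayes factor BF10 as a single number.
#' @export
correlation_bf <- function(r, n,
                           alternative = c("greater", "two.sided", "less"),
                           kappa = 1 / 3) {
  alternative <- match.arg(alternative)
  if (!is_number(r) || abs(r) >= 1) abort("`r` must be a number in (-1, 1).")
  if (!is_number(n) || n < 4) abort("`n` must be at least 4.")
  if (!is_number(kappa) || kappa <= 0 || kappa > 1) {
    abort("`kappa` must be in (0, 1].")
  }
  a <- 1 / kappa
  l0 <- correlation_loglik(0, r, n)
  dens <- function(rho) dbeta((rho + 1) / 2, a, a) / 2
  lims <- switch(alternative,
                 greater = c(0, 1), less = c(-1, 0), two.sided = c(-1, 1))
  mass <- switch(alternative,
                 two.sided = 1,
                 greater = 1 - pbeta(0.5, a, a),
                 less = pbeta(0.5, a, a))
  f <- function(rho) exp(correlation_loglik(rho, r, n) - l0) * dens(rho) / mass
  val <- tryCatch(
    integrate(Vectorize(f), lims[1], lims[2],
              rel.tol = 1e-9, abs.tol = 0, subdivisions = 400L),
    error = function(e) abort(paste0(
      "Bayes factor quadrature failed (r = ", r, ", n = ", n,
      ", kappa = ", kappa, "): ", conditionMessage(e)))
  )
  if (val$message != "OK" && val$message != "") {
    abort(paste0("Bayes factor quadrature did not converge: ", val$message))
  }
  val$value
}

#' Holm step-down adjustment of p-values
#'
#' Step-down Holm correction with an explicitly declared family size: when the
#' analysis family is larger than the vector of p-values supplied (e.g. six
#' preregistered region tests of which some were computed elsewhere), pass
#' `family_size` so the adjustment is performed against the declared family.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param family_size size of the test family (default `length(p)`).
#' @return adjusted p-values, monotone in the order of the raw p-values and
#'   capped at 1.
#' @export
holm_correct <- function(p, family_size = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1].")
  if (family_size < length(p)) {
    abort("`family_size` cannot be smaller than the number of p-values.")
  }
  p.adjust(p, method = "holm", n = family_size)
}

#' Power of the correlation test by the Fisher-z approximation
#'
#' Probability that a correlation test at level `alpha` rejects when the true
#' population correlation is `rho`, using the normal approximation on the
#' Fisher-z scale: for a one-sided positive test,
#' `Phi(atanh(rho) * sqrt(n - 3) - z[1 - alpha])`.
#'
#' @param n sample size (`n >= 4`).
#' @param rho true population correlation, `abs(rho) < 1`.
#' @param alpha test level.
#' @param alternative `"greater"` (one-tailed, positive) or `"two.sided"`.
#' @return the power, a number in `[0, 1]`.
#' @export
power_correlation <- function(n, rho, alpha = 0.05,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is_number(n) || n < 4) abort("`n` must be at least 4.")
  if (!is_number(rho) || abs(rho) >= 1) abort("`rho` must be in (-1, 1).")
  z <- atanh(rho) * sqrt(n - 3)
  if (alternative == "greater") {
    pnorm(z - qnorm(1 - alpha))
  } else {
    zc <- qnorm(1 - alpha / 2)
    pnorm(z - zc) + pnorm(-z - zc)
  }
}

#' Spearman-Brown correction of a split-half correlation
#'
#' Projects the correlation between two test halves to the reliability of the
#' full-length test: `2 r / (1 + r)`.
#'
#' @param r_half split-half correlation in `(-1, 1]`.
#' @return the corrected reliability.
#' @export
spearman_brown <- function(r_half) {
  if (any(r_half <= -1 | r_half > 1)) {
    abort("`r_half` must be in (-1, 1].")
  }
  2 * r_half / (1 + r_half)
}
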