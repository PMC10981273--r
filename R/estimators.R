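# Six causal-effect estimators for two-sample MR. All computation is on the
# beta scale; odds-ratio columns are exp() transforms for reporting only.

new_mr_estimate <- function(method, beta, se, n_snp, extras = list()) {
  pval <- z_pval(beta, se)
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pval = pval,
    or = exp(beta), or_ci_low = exp(beta - Z95 * se), or_ci_high = exp(beta + Z95 * se),
    n_snp = as.integer(n_snp), extras = extras
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g (95%% CI %.4g, %.4g), se = %.4g, p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$se, x$pval, x$n_snp))
  invisible(x)
}

check_h <- function(h, min_snp, method) {
  k <- length(h$snp_ids)
  if (k < min_snp)
    stopf("%s requires at least %d SNP(s); got %d", method, min_snp, k)
  k
}

# Exclude zero-exposure-beta SNPs (undefined Wald ratios) with a warning.
drop_zero_bx <- function(h, method) {
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    warnf("%s: excluding %d SNP(s) with zero exposure beta", method, sum(zero))
    h <- subset_harmonized(h, which(!zero))
  }
  h
}

#' Wald ratio causal estimate (single instrument)
#'
#' `beta = beta_outcome / beta_exposure`, with the first-order delta-method
#' standard error `se_outcome / |beta_exposure|`.
#'
#' @param h a [harmonize()]d set with exactly one SNP.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(h) {
  k <- length(h$snp_ids)
  if (k != 1) stopf("wald_ratio applies to exactly one SNP; got %d (use ivw)", k)
  if (h$beta_exposure == 0) stopf("wald_ratio: zero exposure beta, ratio undefined")
  new_mr_estimate("wald_ratio",
                  beta = h$beta_outcome / h$beta_exposure,
                  se = h$se_outcome / abs(h$beta_exposure),
                  n_snp = 1L)
}

# Core IVW algebra shared by ivw(), leave_one_out() and mr_presso().
ivw_fit <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  k <- length(bx)
  q <- sum(w * (by - beta * bx)^2)  # == sum (bx^2/sy^2) (theta_j - beta)^2
  list(beta = beta, se_fixed = se_fixed, q = q, k = k,
       phi = if (k > 1) max(1, q / (k - 1)) else 1)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights `1/se_outcome^2` (equivalently an inverse-variance
#' meta-analysis of the per-SNP Wald ratios). The fixed-effects standard
#' error is `sqrt(1/sum(w bx^2))`; the random-effects model inflates it by
#' the multiplicative overdispersion factor `sqrt(max(1, Q/(k-1)))`;
#' `"auto"` picks random effects when Cochran's Q has p < 0.05.
#'
#' @param h a [harmonize()]d set with >= 2 SNPs.
#' @param effects_model `"fixed"`, `"random"` or `"auto"`.
#' @return An `mr_estimate`; `extras` records Q and the model used.
#' @export
ivw <- function(h, effects_model = c("fixed", "random", "auto")) {
  effects_model <- match.arg(effects_model)
  check_h(h, 2, "ivw")
  h <- drop_zero_bx(h, "ivw")
  if (all(h$beta_exposure == 0)) stopf("ivw: all exposure betas are zero")
  fit <- ivw_fit(h$beta_exposure, h$beta_outcome, h$se_outcome)
  q_p <- stats::pchisq(fit$q, fit$k - 1, lower.tail = FALSE)
  model <- switch(effects_model,
                  fixed = "fixed", random = "random",
                  auto = if (q_p < 0.05) "random" else "fixed")
  se <- if (model == "random") fit$se_fixed * sqrt(fit$phi) else fit$se_fixed
  new_mr_estimate(paste0("ivw_", model), beta = fit$beta, se = se, n_snp = fit$k,
                  extras = list(q = fit$q, q_pval = q_p, effects_model = model))
}

#' Maximum-likelihood causal estimate
#'
#' Assumes a linear exposure-outcome relationship with per-SNP latent true
#' exposure effects: `bx_j ~ N(xi_j, se_x^2)`, `by_j ~ N(theta xi_j,
#' se_y^2)`. Profiling out the `xi_j` leaves the one-dimensional objective
#' `sum (by - theta bx)^2 / (se_y^2 + theta^2 se_x^2)`, minimised
#' numerically from the IVW starting value; the standard error comes from
#' the observed (profile) information.
#'
#' @param h a [harmonize()]d set with >= 2 SNPs.
#' @return An `mr_estimate`.
#' @export
max_likelihood <- function(h) {
  check_h(h, 2, "max_likelihood")
  bx <- h$beta_exposure; by <- h$beta_outcome
  sx <- h$se_exposure; sy <- h$se_outcome
  nll <- function(theta) 0.5 * sum((by - theta * bx)^2 / (sy^2 + theta^2 * sx^2))
  theta0 <- ivw_fit(bx, by, sy)$beta
  width <- 10 * (abs(theta0) + 1)
  opt <- stats::optim(theta0, nll, method = "Brent",
                      lower = theta0 - width, upper = theta0 + width,
                      control = list(maxit = 500))
  if (opt$convergence != 0)
    stopf("max_likelihood: optimizer failed to converge (last iterate %.6g)", opt$par)
  theta <- opt$par
  eps <- 1e-5 * (abs(theta) + 1)
  info <- (nll(theta + eps) - 2 * nll(theta) + nll(theta - eps)) / eps^2
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  new_mr_estimate("max_likelihood", beta = theta, se = se, n_snp = length(bx))
}

# Weighted least squares with intercept; returns coefficients, analytic ses
# (scaled by the residual sigma, lm convention) and the residual sigma.
wls_with_intercept <- function(x, y, w) {
  X <- cbind(1, x)
  xtwx <- crossprod(X, w * X)
  xtwy <- crossprod(X, w * y)
  coef <- unname(drop(solve(xtwx, xtwy)))
  resid <- y - drop(X %*% coef)
  df <- length(y) - 2
  sigma2 <- if (df > 0) sum(w * resid^2) / df else 0
  se <- sqrt(diag(solve(xtwx)) * max(sigma2, 0))
  list(intercept = coef[1], slope = coef[2],
       se_intercept = se[1], se_slope = se[2],
       sigma = sqrt(max(sigma2, 0)), rss = sum(w * resid^2))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights `1/se_outcome^2`), after orienting all exposure betas
#' non-negative (flipping paired signs). The slope is the pleiotropy-robust
#' causal estimate under the InSIDE assumption; a non-zero intercept
#' indicates directional pleiotropy. Standard errors follow the weighted
#' least-squares convention (scaled by the residual sigma) and p-values use
#' the exact t reference with k - 2 degrees of freedom, so the intercept
#' test is calibrated at small instrument counts; confidence intervals stay
#' on the reporting-wide normal convention.
#'
#' @param h a [harmonize()]d set with >= 3 SNPs.
#' @return An `mr_estimate`; `extras` holds `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p` and the residual `sigma`.
#' @export
egger <- function(h) {
  check_h(h, 3, "egger")
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  bx <- flip * h$beta_exposure
  by <- flip * h$beta_outcome
  fit <- wls_with_intercept(bx, by, 1 / h$se_outcome^2)
  df <- length(bx) - 2
  t_pval <- function(b, se) {
    if (se > 0) 2 * stats::pt(-abs(b / se), df) else as.numeric(b == 0)
  }
  out <- new_mr_estimate("egger", beta = fit$slope, se = fit$se_slope,
                         n_snp = length(bx),
                         extras = list(egger_intercept = fit$intercept,
                                       egger_intercept_se = fit$se_intercept,
                                       egger_intercept_p = t_pval(fit$intercept, fit$se_intercept),
                                       sigma = fit$sigma))
  out$pval <- t_pval(fit$slope, fit$se_slope)
  out
}

# Interpolated weighted quantile of per-SNP ratio estimates. Cumulative
# weight is standardised as (cumsum(w) - w/2) / sum(w); linear interpolation
# between adjacent ordered ratios; an exact boundary returns the lower
# (that) ratio.
weighted_quantile_interp <- function(theta, w, prob = 0.5) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (prob <= p[1]) return(theta[1])
  if (prob >= p[length(p)]) return(theta[length(p)])
  hit <- which(p == prob)
  if (length(hit)) return(theta[hit[1]])
  i <- max(which(p < prob))
  theta[i] + (theta[i + 1] - theta[i]) * (prob - p[i]) / (p[i + 1] - p[i])
}

ratio_and_weights <- function(h) {
  theta <- h$beta_outcome / h$beta_exposure
  w <- h$beta_exposure^2 / h$se_outcome^2  # inverse variance of the ratio
  list(theta = theta, w = w / sum(w))
}

# Parametric bootstrap se: resample betas from their sampling normals and
# recompute the point estimator.
bootstrap_se <- function(h, point_fun, boot_reps, seed) {
  if (boot_reps < 100) warnf("bootstrap: fewer than 100 replicates gives unstable standard errors")
  k <- length(h$snp_ids)
  with_local_seed(seed, {
    est <- vapply(seq_len(boot_reps), function(b) {
      hb <- h
      hb$beta_exposure <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
      hb$beta_outcome <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
      point_fun(hb)
    }, numeric(1))
    stats::sd(est)
  })
}

weighted_median_point <- function(h) {
  rw <- ratio_and_weights(h)
  weighted_quantile_interp(rw$theta, rw$w, 0.5)
}

#' Weighted-median causal estimate
#'
#' The interpolated 50th weighted percentile of the per-SNP Wald ratios with
#' inverse-variance weights; consistent as long as valid instruments carry
#' more than half the weight. The standard error is a seeded parametric
#' bootstrap (resampling betas from their sampling distributions).
#'
#' @param h a [harmonize()]d set with >= 3 SNPs.
#' @param boot_reps bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate`; `extras` records `median_boot_reps`.
#' @export
weighted_median <- function(h, boot_reps = 1000, seed = 1) {
  check_h(h, 3, "weighted_median")
  h <- drop_zero_bx(h, "weighted_median")
  check_h(h, 3, "weighted_median")
  beta <- weighted_median_point(h)
  se <- bootstrap_se(h, weighted_median_point, boot_reps, seed)
  new_mr_estimate("weighted_median", beta = beta, se = se, n_snp = length(h$snp_ids),
                  extras = list(median_boot_reps = boot_reps))
}

weighted_mode_point <- function(h, bandwidth_factor = 1) {
  rw <- ratio_and_weights(h)
  theta <- rw$theta; w <- rw$w
  if (length(unique(theta)) == 1) return(theta[1])
  med <- weighted_quantile_interp(theta, w, 0.5)
  s <- 1.4826 * weighted_quantile_interp(abs(theta - med), w, 0.5)
  if (s == 0) s <- sqrt(sum(w * (theta - sum(w * theta))^2))
  if (s == 0) return(theta[which.max(w)])
  hbw <- bandwidth_factor * 0.9 * s * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * hbw, max(theta) + 3 * hbw, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - theta) / hbw)), numeric(1))
  g0 <- grid[which.max(dens)]
  stats::optimize(function(g) sum(w * stats::dnorm((g - theta) / hbw)),
                  interval = c(g0 - 2 * hbw, g0 + 2 * hbw), maximum = TRUE)$maximum
}

#' Weighted-mode causal estimate
#'
#' Kernel-smoothed (normal kernel) weighted density of the per-SNP Wald
#' ratios; the estimate is the density argmax, consistent when the largest
#' group of instruments with similar ratios is valid. Bandwidth is
#' `bandwidth_factor * 0.9 * s * k^(-1/5)` with `s` the weighted-MAD scale
#' of the ratios. Degenerate (identical) ratios return that common ratio
#' with zero standard error; otherwise the standard error is a seeded
#' parametric bootstrap.
#'
#' @param h a [harmonize()]d set with >= 3 SNPs.
#' @param bandwidth_factor kernel bandwidth multiplier (default 1).
#' @param boot_reps bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate`; `extras` records `mode_bandwidth` factor.
#' @export
weighted_mode <- function(h, bandwidth_factor = 1, boot_reps = 1000, seed = 1) {
  check_h(h, 3, "weighted_mode")
  h <- drop_zero_bx(h, "weighted_mode")
  check_h(h, 3, "weighted_mode")
  beta <- weighted_mode_point(h, bandwidth_factor)
  theta <- h$beta_outcome / h$beta_exposure
  if (length(unique(theta)) == 1) {
    return(new_mr_estimate("weighted_mode", beta = theta[1], se = 0,
                           n_snp = length(theta),
                           extras = list(mode_bandwidth = bandwidth_factor)))
  }
  se <- bootstrap_se(h, function(hb) weighted_mode_point(hb, bandwidth_factor),
                     boot_reps, seed)
  new_mr_estimate("weighted_mode", beta = beta, se = se, n_snp = length(theta),
                  extras = list(mode_bandwidth = bandwidth_factor))
}

#' Run the full estimator battery on a harmonized set
#'
#' Dispatches on instrument count: one SNP gives the Wald ratio only; two
#' SNPs add IVW and maximum likelihood; three or more run all six methods.
#' IVW (with the Q-based auto fixed/random rule) is the primary method.
#'
#' @param h a [harmonize()]d set.
#' @param effects_model IVW effects model (see [ivw()]).
#' @param boot_reps,seed bootstrap settings for median/mode.
#' @return Named list of `mr_estimate` objects.
#' @export
mr_all_methods <- function(h, effects_model = "auto", boot_reps = 1000, seed = 1) {
  k <- length(h$snp_ids)
  if (k == 1) return(list(wald_ratio = wald_ratio(h)))
  out <- list(ivw = ivw(h, effects_model), max_likelihood = max_likelihood(h))
  if (k >= 3) {
    out$egger <- egger(h)
    out$weighted_median <- weighted_median(h, boot_reps, split_seed(seed, 21L))
    out$weighted_mode <- weighted_mode(h, 1, boot_reps, split_seed(seed, 22L))
  }
  out
}
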