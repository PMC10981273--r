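# Multivariable MR and the two-step mediation calculus.

#' Multivariable IVW regression
#'
#' Weighted multiple regression of the outcome betas on the exposure-beta
#' columns (primary exposure first, then covariate exposures), no
#' intercept, weights `1/se_outcome^2`. Each coefficient is that exposure's
#' effect conditional on the others; standard errors follow the weighted
#' least-squares convention with the multiplicative overdispersion floor of
#' the univariable IVW. An all-zero covariate column carries no information
#' and is dropped with a warning (its estimate reported `NA`); genuinely
#' collinear columns are an error naming the offending exposures.
#'
#' @param h a [harmonize()]d set carrying `beta_covariates`/`se_covariates`
#'   (see [harmonize()]'s `covariates` argument). The SNP count must exceed
#'   the number of exposures.
#' @return An `mvmr_result`: `exposure_names`, `betas`, `ses`, `pvals`,
#'   `n_snp`, `conditional_f`.
#' @export
mvmr_ivw <- function(h) {
  if (is.null(h$beta_covariates)) stopf("mvmr_ivw: harmonized set has no covariate exposures")
  X <- cbind(primary = h$beta_exposure, h$beta_covariates)
  colnames(X)[1] <- h$exposure_name %||% "primary"
  k <- nrow(X); p <- ncol(X)
  if (k < p + 1) stopf("mvmr_ivw: need at least %d SNPs for %d exposures; got %d", p + 1, p, k)
  w <- 1 / h$se_outcome^2
  zero_col <- apply(X, 2, function(col) all(col == 0))
  keep_cols <- which(!zero_col)
  if (any(zero_col)) warnf("mvmr_ivw: dropping all-zero exposure column(s): %s",
                           paste(colnames(X)[zero_col], collapse = ", "))
  Xk <- X[, keep_cols, drop = FALSE]
  qrx <- qr(sqrt(w) * Xk)
  if (qrx$rank < ncol(Xk)) {
    dep <- colnames(Xk)[qrx$pivot[(qrx$rank + 1):ncol(Xk)]]
    stopf("mvmr_ivw: collinear exposure columns: %s", paste(dep, collapse = ", "))
  }
  xtwx <- crossprod(Xk, w * Xk)
  coef <- drop(solve(xtwx, crossprod(Xk, w * h$beta_outcome)))
  resid <- h$beta_outcome - drop(Xk %*% coef)
  df <- k - ncol(Xk)
  phi <- max(1, sum(w * resid^2) / df)
  se <- sqrt(diag(solve(xtwx)) * phi)
  betas <- ses <- stats::setNames(rep(NA_real_, p), colnames(X))
  betas[keep_cols] <- coef
  ses[keep_cols] <- se
  # conditional instrument strength: per-exposure F from regressing its
  # betas on the other exposures' betas (weighted), k-1 denominator form
  cf <- stats::setNames(rep(NA_real_, p), colnames(X))
  if (ncol(Xk) > 1) {
    for (j in seq_len(ncol(Xk))) {
      other <- Xk[, -j, drop = FALSE]
      fit <- stats::lm.wfit(other, Xk[, j], w)
      r2c <- 1 - sum(w * fit$residuals^2) / sum(w * (Xk[, j] - stats::weighted.mean(Xk[, j], w))^2)
      cf[keep_cols[j]] <- (1 - r2c) / max(r2c, 1e-12) * (k - ncol(Xk)) / 1
    }
  }
  structure(list(exposure_names = colnames(X), betas = betas, ses = ses,
                 pvals = z_pval(betas, ses), n_snp = as.integer(k),
                 conditional_f = cf),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d SNPs, %d exposures\n", x$n_snp, length(x$betas)))
  print(data.frame(exposure = x$exposure_names, beta = x$betas, se = x$ses,
                   pval = x$pvals, row.names = NULL))
  invisible(x)
}

#' Delta-method interval for a product of two independent estimates
#'
#' First-order variance of `beta_a * beta_b` with zero covariance (the two
#' steps come from non-overlapping samples):
#' `se = sqrt(beta_b^2 se_a^2 + beta_a^2 se_b^2)`; symmetric normal CI and
#' two-sided normal p-value.
#'
#' @param beta_a,se_a first estimate and its standard error (> 0).
#' @param beta_b,se_b second estimate and its standard error (> 0).
#' @param level confidence level (default 0.95).
#' @return List with `effect`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
delta_ci_product <- function(beta_a, se_a, beta_b, se_b, level = 0.95) {
  stopifnot(se_a > 0, se_b > 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect <- beta_a * beta_b
  se <- sqrt(beta_b^2 * se_a^2 + beta_a^2 * se_b^2)
  list(effect = effect, se = se,
       ci_low = effect - z * se, ci_high = effect + z * se,
       pval = z_pval(effect, se))
}

#' Classify mediation evidence
#'
#' `"strong"` when the triangular relationship holds (exposure->outcome,
#' exposure->mediator and mediator->outcome all nominally significant) AND
#' the mediation-effect CI excludes zero; `"potential"` when only the
#' triangle holds; `"not_a_mediator"` otherwise.
#'
#' @param triangle_ok were all three MR tests nominally significant?
#' @param ci_low,ci_high mediation-effect confidence bounds.
#' @return `"strong"`, `"potential"` or `"not_a_mediator"`.
#' @export
classify_evidence <- function(triangle_ok, ci_low, ci_high) {
  if (!isTRUE(triangle_ok)) return("not_a_mediator")
  if (ci_low > 0 || ci_high < 0) "strong" else "potential"
}

#' The mediation arithmetic on total and mediation effects
#'
#' `direct = total - mediation` (so `total = direct + mediation` holds at
#' machine precision) and `proportion = 100 * mediation / total`.
#'
#' @param total_effect total causal effect of exposure on outcome.
#' @param mediation_effect product-of-coefficients mediated effect.
#' @return List with `direct_effect` and `proportion` (percent).
#' @export
mediation_arithmetic <- function(total_effect, mediation_effect) {
  if (total_effect == 0) stopf("mediation proportion undefined: total effect is zero")
  list(direct_effect = total_effect - mediation_effect,
       proportion = 100 * mediation_effect / total_effect)
}

#' Summarise a two-step mediation analysis
#'
#' Combines the univariable total effect (exposure on outcome), step A
#' (exposure on mediator) and step B (the mediator's conditional effect on
#' the outcome from multivariable MR) into the mediated-effect
#' decomposition: `mediation = beta_a * beta_b` with delta-method CI,
#' `direct = total - mediation`, `proportion = 100 * mediation / total`
#' with a delta-method CI on the ratio that is suppressed (`NULL`) whenever
#' the mediation CI spans zero. The evidence tier follows
#' [classify_evidence()]; `consistent_direction` flags whether total,
#' direct and mediation effects share a sign.
#'
#' @param total an `mr_estimate` for exposure -> outcome.
#' @param step_a an `mr_estimate` for exposure -> mediator.
#' @param step_b an [mvmr_ivw()] result; the mediator's conditional estimate
#'   is taken from the exposure named `mediator_name`.
#' @param mediator_name column of `step_b` holding the mediator (default:
#'   second exposure).
#' @param exposure,mediator,outcome trait names for reporting.
#' @param level confidence level.
#' @return A `mediation_result` list mirroring a mediation-table row.
#' @export
mediation_summary <- function(total, step_a, step_b,
                              mediator_name = NULL,
                              exposure = "exposure", mediator = "mediator",
                              outcome = "outcome", level = 0.95) {
  stopifnot(inherits(total, "mr_estimate"), inherits(step_a, "mr_estimate"),
            inherits(step_b, "mvmr_result"))
  mediator_name <- mediator_name %||% step_b$exposure_names[2]
  mi <- match(mediator_name, step_b$exposure_names)
  if (is.na(mi)) stopf("mediation_summary: '%s' not among MVMR exposures", mediator_name)
  beta_a <- step_a$beta; se_a <- step_a$se
  beta_b <- step_b$betas[[mi]]; se_b <- step_b$ses[[mi]]
  d <- delta_ci_product(beta_a, se_a, beta_b, se_b, level)
  triangle_ok <- total$pval < 0.05 && step_a$pval < 0.05 && step_b$pvals[[mi]] < 0.05
  arith <- if (total$beta != 0) mediation_arithmetic(total$beta, d$effect) else
    list(direct_effect = total$beta - d$effect, proportion = NA_real_)
  spans0 <- d$ci_low <= 0 && d$ci_high >= 0
  proportion_ci <- NULL
  if (!spans0 && total$beta != 0) {
    # first-order delta on the ratio mediation/total, independent numerator
    # and denominator (non-overlapping samples)
    r <- d$effect / total$beta
    se_r <- abs(r) * sqrt((d$se / d$effect)^2 + (total$se / total$beta)^2)
    z <- stats::qnorm(1 - (1 - level) / 2)
    proportion_ci <- 100 * c(r - z * se_r, r + z * se_r)
  }
  structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    total_effect = total$beta, total_se = total$se,
    beta_a = beta_a, se_a = se_a, beta_b = beta_b, se_b = se_b,
    mediation_effect = d$effect, mediation_se = d$se,
    ci_low = d$ci_low, ci_high = d$ci_high, mediation_p = d$pval,
    direct_effect = arith$direct_effect,
    proportion = arith$proportion, proportion_ci = proportion_ci,
    evidence = classify_evidence(triangle_ok, d$ci_low, d$ci_high),
    triangle_ok = triangle_ok,
    consistent_direction = sign(total$beta) == sign(arith$direct_effect) &&
      sign(total$beta) == sign(d$effect)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s\n", x$exposure, x$mediator, x$outcome))
  cat(sprintf("  total %.4f | direct %.4f | mediation %.4f (%.4f, %.4f), p = %.4g\n",
              x$total_effect, x$direct_effect, x$mediation_effect,
              x$ci_low, x$ci_high, x$mediation_p))
  pc <- if (is.null(x$proportion_ci)) "" else
    sprintf(" (%.2f%%, %.2f%%)", x$proportion_ci[1], x$proportion_ci[2])
  cat(sprintf("  proportion %.2f%%%s | evidence: %s\n", x$proportion, pc, x$evidence))
  invisible(x)
}
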