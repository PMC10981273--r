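# Heterogeneity, pleiotropy, outlier, influence and direction diagnostics.
# Every function here treats its harmonized_set input as read-only.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (theta_j - theta_IVW)^2` over per-SNP Wald ratios with
#' first-order weights `w_j = beta_exposure_j^2 / se_outcome_j^2`; p-value
#' from the upper tail of chi-square with k - 1 degrees of freedom. SNPs
#' with zero exposure beta have undefined ratios and are excluded with a
#' warning.
#'
#' @param h a [harmonize()]d set with >= 2 SNPs.
#' @return List with `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(h) {
  h <- drop_zero_bx(h, "cochran_q")
  k <- check_h(h, 2, "cochran_q")
  fit <- ivw_fit(h$beta_exposure, h$beta_outcome, h$se_outcome)
  list(q_stat = fit$q, df = k - 1L,
       pval = stats::pchisq(fit$q, k - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept (and its standard error and two-sided p) from the
#' [egger()] regression; a non-zero intercept indicates directional
#' pleiotropy, i.e. a non-zero average direct effect of the instruments on
#' the outcome.
#'
#' @param h a [harmonize()]d set with >= 3 SNPs.
#' @return List with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  e <- egger(h)$extras
  list(intercept = e$egger_intercept, se = e$egger_intercept_se,
       pval = e$egger_intercept_p)
}

# Leave-one-out IVW predictions computed in O(k) from weighted sums.
# Returns per-SNP theta_hat_(-j).
loo_theta <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: global residual test, per-SNP outlier test, iterative removal
#' and distortion test
#'
#' The observed statistic is the weighted residual sum of squares of each
#' SNP against its leave-one-out IVW prediction:
#' `RSS = sum w_j (by_j - theta_(-j) bx_j)^2`, `w_j = 1/se_outcome_j^2`.
#' The null distribution is built by simulating betas from the fitted
#' no-pleiotropy model (`bx* ~ N(bx, se_x^2)`, `by* ~ N(theta_(-j) bx,
#' se_y^2)`) `n_sim` times; `global_p = (1 + #(RSS* >= RSS)) / (n_sim + 1)`.
#' The per-SNP outlier test compares each observed weighted residual with
#' its simulated counterparts (same +1 correction), Bonferroni-adjusted by
#' the instrument count. SNPs are then sorted ascending by outlier p-value
#' and removed one at a time, recomputing the global test after each
#' removal, until the global p exceeds `alpha` or fewer than 4 SNPs remain
#' (flag `unresolved_pleiotropy` in the latter case). The distortion test
#' compares the pre- and post-removal IVW estimates against displacements
#' from removing random same-size SNP subsets; it is advisory only.
#'
#' @param h a [harmonize()]d set with >= 4 SNPs.
#' @param n_sim simulation count (>= 100; default 1000).
#' @param alpha global-test significance level (default 0.05).
#' @param seed integer seed; fixed seed gives a bit-identical report.
#' @return A `presso_report`: `rss_obs`, `global_p`, `n_sim`, `outlier_p`
#'   (Bonferroni-adjusted, named by SNP), `raw_outlier_p`, `removed`
#'   (ordered ids), `removal_trail` (data.frame snp / global_p after each
#'   removal), `distortion_p`, `beta_before`/`beta_after`,
#'   `unresolved_pleiotropy`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, alpha = 0.05, seed = 1) {
  check_h(h, 4, "mr_presso")
  if (n_sim < 100) stopf("mr_presso: n_sim must be >= 100")

  global_test <- function(bx, by, sx, sy, stream) {
    k <- length(bx)
    w <- 1 / sy^2
    th <- loo_theta(bx, by, w)
    res_obs <- w * (by - th * bx)^2
    rss_obs <- sum(res_obs)
    with_local_seed(split_seed(seed, stream), {
      bx_sim <- matrix(stats::rnorm(n_sim * k, rep(bx, each = n_sim),
                                    rep(sx, each = n_sim)), n_sim, k)
      by_sim <- matrix(stats::rnorm(n_sim * k, rep(th * bx, each = n_sim),
                                    rep(sy, each = n_sim)), n_sim, k)
      W <- matrix(w, n_sim, k, byrow = TRUE)
      sxy <- rowSums(W * bx_sim * by_sim)
      sxx <- rowSums(W * bx_sim^2)
      th_sim <- (sxy - W * bx_sim * by_sim) / (sxx - W * bx_sim^2)
      res_sim <- W * (by_sim - th_sim * bx_sim)^2
      rss_sim <- rowSums(res_sim)
      list(rss_obs = rss_obs,
           global_p = (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1),
           outlier_p = (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) / (n_sim + 1))
    })
  }

  k0 <- length(h$snp_ids)
  g0 <- global_test(h$beta_exposure, h$beta_outcome, h$se_exposure, h$se_outcome, 100L)
  raw_p <- stats::setNames(g0$outlier_p, h$snp_ids)
  adj_p <- pmin(1, raw_p * k0)

  removed <- character(0)
  trail <- data.frame(snp = character(0), global_p = numeric(0))
  unresolved <- FALSE
  cur <- h
  global_p <- g0$global_p
  if (global_p <= alpha) {
    order_ids <- h$snp_ids[order(raw_p, h$snp_ids)]
    for (sid in order_ids) {
      if (length(cur$snp_ids) - 1 < 4) { unresolved <- TRUE; break }
      cur <- subset_harmonized(cur, setdiff(cur$snp_ids, sid))
      removed <- c(removed, sid)
      g <- global_test(cur$beta_exposure, cur$beta_outcome,
                       cur$se_exposure, cur$se_outcome,
                       100L + length(removed))
      trail <- rbind(trail, data.frame(snp = sid, global_p = g$global_p))
      global_p <- g$global_p
      if (global_p > alpha) break
    }
    if (global_p <= alpha) unresolved <- TRUE
  }

  beta_before <- ivw_fit(h$beta_exposure, h$beta_outcome, h$se_outcome)$beta
  beta_after <- NULL
  distortion_p <- NULL
  if (length(removed) && length(cur$snp_ids) >= 2) {
    beta_after <- ivw_fit(cur$beta_exposure, cur$beta_outcome, cur$se_outcome)$beta
    d_obs <- beta_before - beta_after
    n_rem <- length(removed)
    if (k0 - n_rem >= 2) {
      d_sim <- with_local_seed(split_seed(seed, 999L), {
        vapply(seq_len(min(n_sim, 1000)), function(b) {
          drop_idx <- sample.int(k0, n_rem)
          f <- ivw_fit(h$beta_exposure[-drop_idx], h$beta_outcome[-drop_idx],
                       h$se_outcome[-drop_idx])
          beta_before - f$beta
        }, numeric(1))
      })
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (length(d_sim) + 1)
    }
  }

  structure(list(
    rss_obs = g0$rss_obs, global_p = g0$global_p, n_sim = n_sim,
    outlier_p = adj_p, raw_outlier_p = raw_p,
    removed = removed, removal_trail = trail,
    final_global_p = global_p,
    distortion_p = distortion_p,
    beta_before = beta_before, beta_after = beta_after,
    unresolved_pleiotropy = unresolved, seed = seed
  ), class = "presso_report")
}

#' @export
print.presso_report <- function(x, ...) {
  cat(sprintf("<presso_report> RSS = %.4g, global p = %.4g (n_sim = %d); %d outlier(s) removed%s\n",
              x$rss_obs, x$global_p, x$n_sim, length(x$removed),
              if (x$unresolved_pleiotropy) " [unresolved pleiotropy]" else ""))
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate (auto fixed/random effects) excluding each
#' SNP in turn, to reveal estimates driven by a single instrument.
#'
#' @param h a [harmonize()]d set with >= 3 SNPs.
#' @return List with `all_snp_beta` and `loo` (data.frame excluded_snp /
#'   beta / se / pval).
#' @export
leave_one_out <- function(h) {
  k <- check_h(h, 3, "leave_one_out")
  full <- ivw(h, "auto")
  rows <- lapply(seq_len(k), function(j) {
    e <- ivw(subset_harmonized(h, setdiff(seq_len(k), j)), "auto")
    data.frame(excluded_snp = h$snp_ids[j], beta = e$beta, se = e$se, pval = e$pval)
  })
  list(all_snp_beta = full$beta, loo = do.call(rbind, rows))
}

#' Steiger directionality test for the instrument set
#'
#' Compares the total instrument variance explained in the exposure against
#' the outcome (per-SNP `2 eaf (1-eaf) beta^2`, each on its own trait's
#' variance-1 scale). The inferred direction is exposure -> outcome when the
#' exposure total is at least as large; the p-value is a z-test on the
#' difference of the implied Fisher-transformed correlations. Equal totals
#' give `direction_ok = TRUE` with p = 1 (no evidence of reversal).
#'
#' @param h a [harmonize()]d set with eaf available.
#' @param n_exp,n_out sample sizes (default: from `h`).
#' @return List with `direction_ok`, `r2_exp_total`, `r2_out_total`, `pval`.
#' @export
steiger_direction <- function(h, n_exp = h$n_exposure, n_out = h$n_outcome) {
  r2e <- sum(r2_per_snp(h$beta_exposure, h$eaf))
  r2o <- sum(r2_per_snp(h$beta_outcome, h$eaf))
  if (r2e == r2o) return(list(direction_ok = TRUE, r2_exp_total = r2e,
                              r2_out_total = r2o, pval = 1))
  z <- (atanh(sqrt(min(r2e, 1 - 1e-12))) - atanh(sqrt(min(r2o, 1 - 1e-12)))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(direction_ok = r2e > r2o, r2_exp_total = r2e, r2_out_total = r2o,
       pval = 2 * stats::pnorm(-abs(z)))
}
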