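# Seeded calibration experiments: frequentist operating characteristics of
# the estimators and diagnostics under the synthetic generator's known
# ground truth. These are the package's own validation surface; the same
# functions drive the test suite and the reproduction script.
#
# Experiments run in a strong-instrument regime (sigma_b = 0.1 at
# n = 50,000 per trait, per-SNP F >> 10) so that estimator properties are
# measured without weak-instrument regression dilution; the generator's
# default sigma_b = 0.03 deliberately straddles F = 10 instead.

calib_truth <- function(seed, m = 50, theta_direct = 0.1, beta_a = 0.5,
                        beta_b = 0.4, sigma_b = 0.1, n = 50000, ...) {
  simulation_truth(m_instruments = m, theta_direct = theta_direct,
                   beta_a = beta_a, beta_b = beta_b, sigma_b = sigma_b,
                   n_exp = n, n_med = n, n_out = n, seed = seed, ...)
}

# Harmonized exposure-outcome set over the true instrument ids.
h_on_instruments <- function(study, outcome = "outcome") {
  ids <- names(study$truth$snp_role)[study$truth$snp_role == "instrument"]
  harmonize(study$exposure, study[[outcome]], snp_ids = ids)
}

#' Calibration: IVW bias over valid instruments
#'
#' Repeatedly simulates studies with 50 valid instruments at n = 50,000 per
#' trait and no pleiotropy, estimates the total effect by fixed-effects IVW
#' over the true instruments, and reports the mean deviation from the true
#' total effect (0.3 under the default generating values).
#'
#' @param n_reps replicates (default 200).
#' @param seed integer seed.
#' @return List with `bias`, `mc_se` (Monte-Carlo SE of the mean),
#'   `theta_total`, `n_reps`.
#' @export
calib_ivw_bias <- function(n_reps = 200, seed = 1) {
  est <- vapply(seq_len(n_reps), function(r) {
    st <- simulate_summary_stats(calib_truth(split_seed(seed, r)))
    ivw(h_on_instruments(st), "fixed")$beta
  }, numeric(1))
  theta <- calib_truth(1)$theta_total
  list(bias = mean(est) - theta, mc_se = stats::sd(est) / sqrt(n_reps),
       theta_total = theta, n_reps = n_reps)
}

#' Calibration: type-I error of Cochran's Q and the Egger intercept test
#'
#' Null replicates (all causal effects zero, valid instruments, no
#' pleiotropy); reports the fraction of replicates where each test rejects
#' at 0.05. Both should sit within Monte-Carlo error of the nominal 5%.
#'
#' @param n_reps replicates (default 500).
#' @param seed integer seed.
#' @return List with `q_rate`, `egger_rate`, `mc_se` (binomial SE at 5%),
#'   `n_reps`.
#' @export
calib_type1_error <- function(n_reps = 500, seed = 1) {
  hit <- vapply(seq_len(n_reps), function(r) {
    st <- simulate_summary_stats(calib_truth(split_seed(seed, 10000 + r),
                                             theta_direct = 0, beta_a = 0, beta_b = 0))
    h <- h_on_instruments(st)
    c(q = cochran_q(h)$pval < 0.05, egger = egger_intercept_test(h)$pval < 0.05)
  }, logical(2))
  list(q_rate = mean(hit["q", ]), egger_rate = mean(hit["egger", ]),
       mc_se = sqrt(0.05 * 0.95 / n_reps), n_reps = n_reps)
}

#' Calibration: MR-PRESSO detection of a single injected outlier
#'
#' Each replicate injects a 10-standard-error shift into one instrument's
#' outcome beta and runs [mr_presso()]. Reports the fraction of replicates
#' where that SNP has the smallest outlier p-value (and is removed first),
#' and the fraction where iterative removal restores the global p above
#' 0.05.
#'
#' @param n_reps replicates (default 100).
#' @param n_sim MR-PRESSO simulation count (default 1000).
#' @param m instruments per replicate (default 20).
#' @param seed integer seed.
#' @return List with `first_flag_rate`, `restored_rate`, `clean_rate`
#'   (fraction of matching outlier-free replicates with global p > 0.05),
#'   `n_reps`.
#' @export
calib_presso_outlier <- function(n_reps = 100, n_sim = 1000, m = 20, seed = 1) {
  res <- vapply(seq_len(n_reps), function(r) {
    st <- simulate_summary_stats(calib_truth(split_seed(seed, 20000 + r), m = m))
    clean <- mr_presso(h_on_instruments(st), n_sim = n_sim, alpha = 0.05,
                       seed = split_seed(seed, 30000 + r))
    mag <- 10 * stats::median(st$outcome$se)
    st <- inject_outliers(st, k = 1, magnitude = mag)
    pr <- mr_presso(h_on_instruments(st), n_sim = n_sim, alpha = 0.05,
                    seed = split_seed(seed, 30000 + r))
    target <- st$truth$outlier_ids
    first <- names(which.min(pr$raw_outlier_p)) == target &&
      length(pr$removed) >= 1 && pr$removed[1] == target
    c(first = first, restored = pr$final_global_p > 0.05,
      clean = clean$global_p > 0.05)
  }, logical(3))
  list(first_flag_rate = mean(res["first", ]),
       restored_rate = mean(res["restored", ]),
       clean_rate = mean(res["clean", ]), n_reps = n_reps)
}

#' Calibration: Steiger filtering of reverse-causal SNPs
#'
#' Simulates panels of reverse-causal SNPs (primary effect on the outcome,
#' none on the exposure; per-allele scale sigma_b = 0.03 at n = 50,000),
#' selects candidate instruments on the OUTCOME p-values — the discovery
#' route that lets reverse-causal SNPs into an instrument set — and reports
#' the fraction of selected reverse SNPs that Steiger filtering removes.
#'
#' @param n_reps replicates (default 20).
#' @param n_reverse reverse-causal SNPs per replicate (default 40).
#' @param seed integer seed.
#' @return List with `removal_rate`, `n_selected` (total selected across
#'   replicates), `n_reps`.
#' @export
calib_steiger_reverse <- function(n_reps = 20, n_reverse = 40, seed = 1) {
  removed <- 0L; selected <- 0L
  for (r in seq_len(n_reps)) {
    st <- simulate_summary_stats(calib_truth(split_seed(seed, 40000 + r),
                                             m = 1, sigma_b = 0.03,
                                             n_reverse_snps = n_reverse))
    rev_ids <- names(st$truth$snp_role)[st$truth$snp_role == "reverse"]
    cand <- suppressWarnings(filter_by_pvalue(st$outcome, 1e-5))
    cand <- intersect(cand, rev_ids)
    if (!length(cand)) next
    h <- harmonize(st$exposure, st$outcome, snp_ids = cand)
    kept <- steiger_filter(h)
    selected <- selected + length(cand)
    removed <- removed + length(attr(kept, "removed"))
  }
  list(removal_rate = if (selected) removed / selected else NA_real_,
       n_selected = selected, n_reps = n_reps)
}

#' Calibration: mediation-proportion recovery
#'
#' Simulates the three-trait system at (theta_direct = 0.1, beta_a = 0.5,
#' beta_b = 0.4) with 50 exposure and 50 mediator-specific instruments,
#' runs the two-step mediation over the known instruments — total effect
#' and step A by IVW, step B by multivariable IVW over the combined
#' instrument panel — and reports the mean estimated mediation proportion,
#' to be compared with the true 100 * beta_a * beta_b / theta_total =
#' 66.67%.
#'
#' @param n_reps replicates (default 200).
#' @param seed integer seed.
#' @return List with `mean_proportion`, `mc_se`, `true_proportion`,
#'   `n_reps`.
#' @export
calib_mediation_recovery <- function(n_reps = 200, seed = 1) {
  tr0 <- calib_truth(1, m_mediator_instruments = 50)
  true_prop <- 100 * tr0$beta_a * tr0$beta_b / tr0$theta_total
  prop <- vapply(seq_len(n_reps), function(r) {
    st <- simulate_summary_stats(calib_truth(split_seed(seed, 50000 + r),
                                             m_mediator_instruments = 50))
    total <- ivw(h_on_instruments(st), "fixed")
    step_a <- ivw(h_on_instruments(st, "mediator"), "fixed")
    all_ids <- names(st$truth$snp_role)[st$truth$snp_role %in%
                                          c("instrument", "mediator_instrument")]
    hm <- harmonize(st$exposure, st$outcome, snp_ids = all_ids,
                    covariates = list(mediator = st$mediator))
    ms <- mediation_summary(total, step_a, mvmr_ivw(hm), mediator_name = "mediator")
    ms$proportion
  }, numeric(1))
  list(mean_proportion = mean(prop), mc_se = stats::sd(prop) / sqrt(n_reps),
       true_proportion = true_prop, n_reps = n_reps)
}
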