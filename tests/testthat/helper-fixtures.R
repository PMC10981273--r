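# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

# A summary_dataset from parallel vectors, with sensible defaults.
make_sumstats <- function(snp, beta, se, pval = NULL, eaf = 0.3,
                          ea = "A", oa = "G", chrom = "1",
                          pos = NULL, n = 10000,
                          trait_name = "trait", trait_category = "microbiota",
                          trait_type = "continuous") {
  k <- length(snp)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  pval <- pmax(pval, .Machine$double.xmin)
  summary_dataset(
    data.frame(snp = snp, chrom = rep_len(chrom, k),
               pos = pos %||% seq(1e6, by = 1e6, length.out = k),
               effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
               eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
               pval = pval, n = rep_len(n, k), stringsAsFactors = FALSE),
    trait_name = trait_name, trait_category = trait_category,
    trait_type = trait_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A harmonized_set built directly from effect vectors (bypasses allele
# bookkeeping; for estimator/diagnostic tests).
make_h <- function(bx, by, sy, sx = rep(1e-4, length(bx)),
                   eaf = rep(0.3, length(bx)),
                   n_exp = 50000, n_out = 50000,
                   snp = sprintf("rs%03d", seq_along(bx))) {
  structure(list(
    snp_ids = snp, beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy, eaf = eaf,
    eaf_outcome = eaf,
    pval_exposure = 2 * pnorm(-abs(bx / sx)),
    pval_outcome = 2 * pnorm(-abs(by / sy)),
    palindromic_dropped = character(0),
    excluded = data.frame(snp = character(0), reason = character(0)),
    n_exposure = n_exp, n_outcome = n_out,
    exposure_name = "exposure", outcome_name = "outcome",
    exposure_category = "microbiota", outcome_type = "continuous"
  ), class = "harmonized_set")
}

# The 3-SNP perfectly consistent fixture (all Wald ratios = 2).
consistent_h <- function() {
  make_h(bx = c(0.1, 0.2, 0.1), by = c(0.2, 0.4, 0.2), sy = c(0.1, 0.1, 0.2))
}

# Strong-instrument simulated study used across calibration-style tests.
quick_study <- function(seed, m = 50, theta_direct = 0.1, beta_a = 0.5,
                        beta_b = 0.4, sigma_b = 0.1, n = 50000, ...) {
  simulate_summary_stats(simulation_truth(
    m_instruments = m, theta_direct = theta_direct, beta_a = beta_a,
    beta_b = beta_b, sigma_b = sigma_b,
    n_exp = n, n_med = n, n_out = n, seed = seed, ...))
}

instrument_ids <- function(study, roles = "instrument") {
  names(study$truth$snp_role)[study$truth$snp_role %in% roles]
}
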