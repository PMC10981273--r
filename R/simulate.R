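#' Ground truth for a simulated three-trait GWAS system
#'
#' Defines an exposure -> mediator -> outcome causal system with known
#' effects. The total causal effect of exposure on outcome decomposes
#' exactly as `theta_total = theta_direct + beta_a * beta_b`. Per-SNP direct
#' effects on the outcome (horizontal pleiotropy) can be balanced
#' (zero-mean) or directional (mean `pleiotropy_mean > 0`) and affect a
#' `prop_invalid` fraction of the instruments. Null SNPs carry no effect on
#' any trait; reverse-causal SNPs act primarily on the outcome and not at
#' all on the exposure. Mediator-specific instruments (SNPs acting on the
#' mediator but not the exposure) identify the multivariable-MR step of the
#' mediation analysis.
#'
#' Defaults emulate the statistical structure of the consortia this kind of
#' analysis draws on: 18,340-sample microbiota exposures, 8,299-sample
#' metabolite mediators, ~700,000-sample anthropometric outcomes, and
#' per-allele effect sizes (`sigma_b = 0.03`) whose instrument F-statistics
#' straddle the conventional F = 10 threshold.
#'
#' @param m_instruments number of valid exposure instruments (>= 1).
#' @param theta_direct direct exposure->outcome effect.
#' @param beta_a exposure->mediator effect.
#' @param beta_b mediator->outcome effect conditional on exposure.
#' @param sigma_b SD of true per-allele instrument effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd SD of per-SNP direct-on-outcome effects.
#' @param pleiotropy_mean mean pleiotropic effect (directional mode only).
#' @param prop_invalid fraction of instruments carrying pleiotropy, in [0,1].
#' @param n_exp,n_med,n_out GWAS sample sizes (>= 100).
#' @param n_null_snps SNPs with no effect on any trait.
#' @param n_reverse_snps SNPs whose primary effect is on the outcome.
#' @param m_mediator_instruments SNPs acting directly on the mediator.
#' @param seed integer seed; every random draw descends from it.
#' @return A `simulation_truth` list; `theta_total` is computed from the
#'   identity above.
#' @export
simulation_truth <- function(m_instruments = 20, theta_direct = 0.1,
                             beta_a = 0.5, beta_b = 0.4, sigma_b = 0.03,
                             pleiotropy_mode = c("none", "balanced", "directional"),
                             pleiotropy_sd = 0, pleiotropy_mean = 0,
                             prop_invalid = 0,
                             n_exp = 18340, n_med = 8299, n_out = 700000,
                             n_null_snps = 0, n_reverse_snps = 0,
                             m_mediator_instruments = 0, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!is_count(m_instruments) || m_instruments < 1) stopf("simulation_truth: m_instruments must be >= 1")
  if (min(n_exp, n_med, n_out) < 100) stopf("simulation_truth: sample sizes must be >= 100")
  if (prop_invalid < 0 || prop_invalid > 1) stopf("simulation_truth: prop_invalid must lie in [0, 1]")
  if (pleiotropy_mode != "none" && pleiotropy_sd <= 0)
    stopf("simulation_truth: pleiotropy_sd must be > 0 when pleiotropy_mode is '%s'", pleiotropy_mode)
  if (pleiotropy_mode == "directional" && pleiotropy_mean <= 0)
    stopf("simulation_truth: pleiotropy_mean must be > 0 in directional mode")
  structure(list(
    m_instruments = as.integer(m_instruments),
    theta_direct = theta_direct, beta_a = beta_a, beta_b = beta_b,
    theta_total = theta_direct + beta_a * beta_b,
    sigma_b = sigma_b,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
    pleiotropy_mean = pleiotropy_mean, prop_invalid = prop_invalid,
    n_exp = n_exp, n_med = n_med, n_out = n_out,
    n_null_snps = as.integer(n_null_snps),
    n_reverse_snps = as.integer(n_reverse_snps),
    m_mediator_instruments = as.integer(m_mediator_instruments),
    seed = as.integer(seed)
  ), class = "simulation_truth")
}

# Standard error of a per-allele estimate for a variance-1 trait.
se_from_n_eaf <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

#' Simulate three-trait GWAS summary statistics with known ground truth
#'
#' Generates exposure, mediator and outcome summary datasets over a shared
#' SNP panel. For SNP j with true per-allele exposure effect `b_j` (drawn
#' `N(0, sigma_b^2)` for instruments, 0 for null SNPs), the true mediator
#' effect is `beta_a * b_j` and the true outcome effect is
#' `theta_direct * b_j + beta_b * beta_a * b_j + alpha_j`, where `alpha_j`
#' is the SNP's pleiotropic direct effect (oriented relative to the
#' exposure-increasing allele, so "directional" pleiotropy has a non-zero
#' mean in the orientation pleiotropy-robust estimators use).
#' Mediator-specific instruments
#' have a direct mediator effect `d_j ~ N(0, sigma_b^2)` propagating to the
#' outcome as `beta_b * d_j`; reverse-causal SNPs have a direct outcome
#' effect only. Standard errors follow the variance-1 approximation
#' `1/sqrt(2 n eaf (1-eaf))`, observed betas add independent `N(0, se^2)`
#' noise per trait (non-overlapping samples), and p-values are two-sided
#' normal. Fixed seed gives bit-identical output; each dataset's noise
#' stream is split from the base seed so the three cohorts are independent.
#'
#' @param truth a [simulation_truth()].
#' @return A `simulated_study`: list of `exposure`, `mediator`, `outcome`
#'   ([summary_dataset()]s sharing snp ids), the `truth` (augmented with the
#'   per-SNP true effect vectors and SNP roles), and `ld` (`NULL`; attach a
#'   toy [ld_matrix()] for clumping tests).
#' @export
simulate_summary_stats <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  m <- truth$m_instruments
  n_tot <- m + truth$m_mediator_instruments + truth$n_null_snps + truth$n_reverse_snps
  role <- rep(c("instrument", "mediator_instrument", "null", "reverse"),
              c(m, truth$m_mediator_instruments, truth$n_null_snps, truth$n_reverse_snps))
  snp <- sprintf("rs%06d", seq_len(n_tot))
  chrom <- as.character(rep_len(1:22, n_tot))
  pos <- 1e6 * (seq_len(n_tot) %/% 22 + 1) + seq_len(n_tot)

  draw <- function(stream, expr) with_local_seed(split_seed(truth$seed, stream), expr)

  eaf <- draw(1L, stats::runif(n_tot, 0.05, 0.95))
  b <- numeric(n_tot)
  b[role == "instrument"] <- draw(2L, stats::rnorm(m, 0, truth$sigma_b))
  d <- numeric(n_tot)  # direct mediator effects
  if (truth$m_mediator_instruments > 0)
    d[role == "mediator_instrument"] <- draw(3L, stats::rnorm(truth$m_mediator_instruments, 0, truth$sigma_b))
  g <- numeric(n_tot)  # direct outcome effects of reverse-causal SNPs
  if (truth$n_reverse_snps > 0)
    g[role == "reverse"] <- draw(4L, stats::rnorm(truth$n_reverse_snps, 0, truth$sigma_b))

  alpha <- numeric(n_tot)
  if (truth$pleiotropy_mode != "none" && truth$prop_invalid > 0) {
    n_invalid <- round(truth$prop_invalid * m)
    inv <- which(role == "instrument")[seq_len(n_invalid)]
    mu <- if (truth$pleiotropy_mode == "directional") truth$pleiotropy_mean else 0
    alpha[inv] <- draw(5L, stats::rnorm(n_invalid, mu, truth$pleiotropy_sd))
    truth$invalid_ids <- snp[inv]
  }

  true_exp <- b
  true_med <- truth$beta_a * b + d
  # pleiotropic direct effects are defined relative to the
  # exposure-increasing allele (the orientation under which "directional"
  # means a non-zero mean), then mapped back to the reported effect allele
  orient <- ifelse(b < 0, -1, 1)
  true_out <- truth$theta_direct * b + truth$beta_b * true_med + orient * alpha + g

  make <- function(true_beta, n, stream, name, category, type) {
    se <- se_from_n_eaf(n, eaf)
    beta <- true_beta + draw(stream, stats::rnorm(n_tot, 0, se))
    summary_dataset(
      data.frame(snp = snp, chrom = chrom, pos = pos,
                 effect_allele = "A", other_allele = "G",
                 eaf = eaf, beta = beta, se = se,
                 pval = z_pval(beta, se), n = n,
                 stringsAsFactors = FALSE),
      trait_name = name, trait_category = category, trait_type = type)
  }
  truth$true_beta_exposure <- true_exp
  truth$true_beta_mediator <- true_med
  truth$true_beta_outcome <- true_out
  truth$snp_role <- stats::setNames(role, snp)

  structure(list(
    exposure = make(true_exp, truth$n_exp, 11L, "exposure", "microbiota", "continuous"),
    mediator = make(true_med, truth$n_med, 12L, "mediator", "metabolite", "continuous"),
    outcome = make(true_out, truth$n_out, 13L, "outcome", "obesity", "continuous"),
    truth = truth, ld = NULL
  ), class = "simulated_study")
}

#' Inject outlier effects into a simulated study's outcome betas
#'
#' Adds `magnitude` to the observed outcome beta of the first `k` valid
#' instruments, recording their ids in `truth$outlier_ids`. Used to exercise
#' outlier-detection diagnostics (e.g. the horizontal-pleiotropy residual
#' tests) against a known answer.
#'
#' @param study a `simulated_study`.
#' @param k number of instruments to perturb (`k = 0` is a no-op);
#'   must be < the number of instruments.
#' @param magnitude value added to each perturbed outcome beta. A vector of
#'   length `k` gives per-SNP (e.g. opposite-signed) shifts.
#' @return The modified `simulated_study`.
#' @export
inject_outliers <- function(study, k, magnitude) {
  stopifnot(inherits(study, "simulated_study"))
  if (!is_count(k) || k < 0 || k >= study$truth$m_instruments)
    stopf("inject_outliers: k must satisfy 0 <= k < m_instruments")
  if (k == 0) return(study)
  ids <- names(study$truth$snp_role)[study$truth$snp_role == "instrument"][seq_len(k)]
  idx <- match(ids, study$outcome$snp)
  shift <- rep_len(magnitude, k)
  study$outcome$beta[idx] <- study$outcome$beta[idx] + shift
  study$outcome$pval[idx] <- z_pval(study$outcome$beta[idx], study$outcome$se[idx])
  study$truth$outlier_ids <- ids
  study
}

#' Attach a block-diagonal toy LD matrix to a simulated study
#'
#' Splits the SNP panel into consecutive blocks of `block_size` SNPs on the
#' same chromosome with constant within-block correlation `r_within` (zero
#' between blocks), and places block members within `span_kb` of each other
#' so clumping windows bind.
#'
#' @param study a `simulated_study`.
#' @param block_size SNPs per LD block.
#' @param r_within within-block pairwise correlation.
#' @param span_kb positional span of a block in kilobases.
#' @return The study with `ld` set and positions/chromosomes rewritten to
#'   match the block layout (identically in all three datasets).
#' @export
attach_block_ld <- function(study, block_size = 2, r_within = 0.5, span_kb = 100) {
  stopifnot(inherits(study, "simulated_study"))
  snp <- study$exposure$snp
  n <- length(snp)
  block <- (seq_len(n) - 1L) %/% block_size
  chrom <- as.character(block %% 22 + 1)
  within <- (seq_len(n) - 1L) %% block_size
  pos <- 1e6 + (block %/% 22) * 1e8 + within * (span_kb * 1000 / max(1, block_size - 1))
  r <- outer(block, block, function(a, b) ifelse(a == b, r_within, 0))
  diag(r) <- 1
  for (tr in c("exposure", "mediator", "outcome")) {
    study[[tr]]$chrom <- chrom
    study[[tr]]$pos <- pos
  }
  study$ld <- ld_matrix(r, snp_ids = snp, pos = pos, chrom = chrom)
  study
}

#' Write a simulated study to a directory
#'
#' Emits `exposure.tsv`, `mediator.tsv`, `outcome.tsv` (and `ld.tsv` when
#' present) plus `truth.json` recording the generating parameters.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in c("exposure", "mediator", "outcome"))
    write_summary_stats(study[[tr]], file.path(dir, paste0(tr, ".tsv")))
  if (!is.null(study$ld)) write_ld_matrix(study$ld, file.path(dir, "ld.tsv"))
  tr <- study$truth
  tr$snp_role <- NULL
  jsonlite::write_json(tr[!vapply(tr, is.null, TRUE)],
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
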