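#' Instrument-selection configuration
#'
#' Thresholds for the six-rule instrument-selection sequence: (1) exposure
#' p-value threshold (locus-wide 1e-5 by default, genome-wide 5e-8 for large
#' GWAS), (2) exclusion of outcome-associated SNPs (p < 0.05), (3) LD
#' clumping (presets: r2 < 0.01 within 500 kb, or r2 < 0.001 within
#' 10,000 kb), (4) iterative MR-PRESSO outlier removal, (5) weak-instrument
#' F threshold, (6) Steiger filtering.
#'
#' @param p_exposure_threshold exposure association threshold (strict `<`).
#' @param p_outcome_exclude outcome association exclusion threshold.
#' @param clump_preset `"strict"` (r2 0.001 / 10,000 kb, default) or
#'   `"loose"` (r2 0.01 / 500 kb); ignored when `clump_r2`/`clump_window_kb`
#'   are given explicitly.
#' @param clump_r2,clump_window_kb explicit clumping parameters.
#' @param f_min minimum instrument F-statistic (default 10).
#' @param presso_alpha MR-PRESSO global-test significance level.
#' @param presso_nsim MR-PRESSO simulation count.
#' @param steiger_enabled run Steiger filtering (rule 6)?
#' @param steiger_gate optional significance gate for per-SNP Steiger
#'   removal (`NULL` = blunt point comparison).
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_exposure_threshold = 1e-5,
                             p_outcome_exclude = 0.05,
                             clump_preset = c("strict", "loose"),
                             clump_r2 = NULL, clump_window_kb = NULL,
                             f_min = 10, presso_alpha = 0.05,
                             presso_nsim = 1000,
                             steiger_enabled = TRUE, steiger_gate = NULL) {
  clump_preset <- match.arg(clump_preset)
  preset <- switch(clump_preset,
                   strict = list(r2 = 0.001, window = 10000),
                   loose = list(r2 = 0.01, window = 500))
  cfg <- list(
    p_exposure_threshold = p_exposure_threshold,
    p_outcome_exclude = p_outcome_exclude,
    clump_r2 = clump_r2 %||% preset$r2,
    clump_window_kb = clump_window_kb %||% preset$window,
    f_min = f_min, presso_alpha = presso_alpha, presso_nsim = presso_nsim,
    steiger_enabled = isTRUE(steiger_enabled), steiger_gate = steiger_gate
  )
  for (p in c("p_exposure_threshold", "p_outcome_exclude", "presso_alpha"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) stopf("selection_config: %s must lie in (0, 1)", p)
  if (cfg$clump_window_kb <= 0) stopf("selection_config: clump window must be > 0")
  structure(cfg, class = "selection_config")
}

#' Rule 1: select SNPs below the exposure significance threshold
#'
#' Strict inequality; returned sorted ascending by exposure p-value with a
#' lexicographic snp-id tie-break (deterministic ordering downstream).
#'
#' @param exposure a [summary_dataset()].
#' @param threshold p-value threshold in (0, 1).
#' @return Character vector of snp ids (possibly empty, with a warning).
#' @export
filter_by_pvalue <- function(exposure, threshold = 1e-5) {
  if (threshold <= 0 || threshold >= 1) stopf("filter_by_pvalue: threshold must lie in (0, 1)")
  keep <- exposure[exposure$pval < threshold, c("snp", "pval")]
  if (!nrow(keep)) warnf("filter_by_pvalue: no SNP passes p < %g", threshold)
  keep$snp[order(keep$pval, keep$snp)]
}

#' Rule 2: exclude candidate SNPs associated with the outcome
#'
#' Removes candidates whose outcome p-value is (strictly) below `p_cut`.
#' A candidate absent from the outcome dataset cannot be tested and is
#' retained with a warning.
#'
#' @param candidates snp-id vector (ordering preserved).
#' @param outcome a [summary_dataset()].
#' @param p_cut exclusion threshold.
#' @return Filtered snp ids, with attribute `removed`.
#' @export
exclude_outcome_associated <- function(candidates, outcome, p_cut = 0.05) {
  if (p_cut <= 0 || p_cut >= 1) stopf("exclude_outcome_associated: p_cut must lie in (0, 1)")
  idx <- match(candidates, outcome$snp)
  if (anyNA(idx)) warnf("exclude_outcome_associated: %d candidate(s) absent from outcome dataset; retained",
                        sum(is.na(idx)))
  p_out <- outcome$pval[idx]
  drop <- !is.na(p_out) & p_out < p_cut
  structure(candidates[!drop], removed = candidates[drop])
}

#' Rule 3: greedy LD clumping
#'
#' Candidates are visited in ascending exposure p-value order (snp-id
#' tie-break). A SNP is kept unless it lies within `window_kb` (center to
#' center) of an already-kept SNP on the same chromosome AND its squared LD
#' correlation with that SNP is at least `r2_max`; removed SNPs record
#' their index SNP. Output is therefore invariant to the input order of
#' `candidates`.
#'
#' @param candidates snp-id vector, all present in `ld`.
#' @param exposure a [summary_dataset()] supplying p-values, chromosomes and
#'   positions.
#' @param ld an [ld_matrix()].
#' @param r2_max clumping r-squared threshold.
#' @param window_kb window size in kilobases.
#' @return Kept snp ids in p-value order, with attribute `removed`
#'   (data.frame snp / index_snp).
#' @export
clump <- function(candidates, exposure, ld, r2_max = 0.001, window_kb = 10000) {
  missing_ld <- setdiff(candidates, ld$snp_ids)
  if (length(missing_ld))
    stopf("clump: candidate(s) missing from LD matrix: %s", paste(missing_ld, collapse = ", "))
  ei <- match(candidates, exposure$snp)
  if (anyNA(ei)) stopf("clump: candidate(s) missing from exposure dataset")
  ord <- order(exposure$pval[ei], candidates)
  snps <- candidates[ord]
  chrom <- exposure$chrom[ei][ord]
  pos <- exposure$pos[ei][ord]
  kept <- character(0); kept_chrom <- character(0); kept_pos <- numeric(0)
  removed <- data.frame(snp = character(0), index_snp = character(0))
  for (i in seq_along(snps)) {
    clash <- which(kept_chrom == chrom[i] &
                     abs(kept_pos - pos[i]) <= window_kb * 1000 &
                     ld$r[snps[i], kept]^2 >= r2_max)
    if (length(clash)) {
      removed <- rbind(removed, data.frame(snp = snps[i], index_snp = kept[clash[1]]))
    } else {
      kept <- c(kept, snps[i]); kept_chrom <- c(kept_chrom, chrom[i]); kept_pos <- c(kept_pos, pos[i])
    }
  }
  structure(kept, removed = removed)
}

# Per-SNP variance explained on a variance-1 trait scale.
r2_per_snp <- function(beta, eaf, n = NULL) {
  if (anyNA(eaf)) stopf("effect-allele frequency is required to compute variance explained")
  2 * eaf * (1 - eaf) * beta^2
}

#' Rule 5: instrument-set F-statistic
#'
#' Per-SNP variance explained is `2 eaf (1 - eaf) beta^2` on a variance-1
#' trait scale; the set-level R-squared is their sum, and
#' `F = (R2 (n - k - 1)) / (k (1 - R2))` with `k` instruments and sample
#' size `n`.
#'
#' @param instruments snp-id vector (k >= 1).
#' @param exposure a [summary_dataset()] with eaf available.
#' @param n sample size (defaults to the dataset's median `n`); must exceed
#'   `k + 1`.
#' @return List with `f`, `r2_total`, `k`, `n` and per-SNP `r2`.
#' @export
compute_f_statistic <- function(instruments, exposure, n = NULL) {
  idx <- match(instruments, exposure$snp)
  if (anyNA(idx)) stopf("compute_f_statistic: instrument(s) missing from exposure dataset")
  k <- length(instruments)
  if (k < 1) stopf("compute_f_statistic: need at least one instrument")
  n <- n %||% stats::median(exposure$n, na.rm = TRUE)
  if (is.na(n) || n <= k + 1) stopf("compute_f_statistic: sample size must exceed k + 1")
  r2 <- r2_per_snp(exposure$beta[idx], exposure$eaf[idx])
  r2_total <- sum(r2)
  f <- (r2_total * (n - k - 1)) / (k * (1 - r2_total))
  list(f = f, r2_total = r2_total, k = k, n = n,
       r2 = stats::setNames(r2, instruments))
}

#' Rule 6: Steiger filtering of reverse-causal instruments
#'
#' Removes SNPs explaining more outcome than exposure variance
#' (`r2_outcome > r2_exposure`, each on its own trait's variance-1 scale).
#' With `significance_gate` set, a SNP is removed only when the Steiger
#' z-test comparing the two implied correlations is also significant at the
#' gate; with very small samples (n <= 3) the z-test is impossible and the
#' blunt point comparison is used with a warning.
#'
#' @param h a [harmonize()]d set with eaf available.
#' @param n_exp,n_out exposure/outcome sample sizes (default: from `h`).
#' @param significance_gate optional p-value gate; `NULL` = point comparison.
#' @return Kept snp ids, with attribute `removed`.
#' @export
steiger_filter <- function(h, n_exp = h$n_exposure, n_out = h$n_outcome,
                           significance_gate = NULL) {
  r2_exp <- r2_per_snp(h$beta_exposure, h$eaf)
  r2_out <- r2_per_snp(h$beta_outcome, h$eaf)
  flag <- r2_out > r2_exp
  if (!is.null(significance_gate)) {
    if (min(n_exp, n_out) <= 3) {
      warnf("steiger_filter: n <= 3, cannot compute z-test; using point comparison")
    } else {
      z <- (atanh(sqrt(pmin(r2_exp, 1 - 1e-12))) - atanh(sqrt(pmin(r2_out, 1 - 1e-12)))) /
        sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
      p <- 2 * stats::pnorm(-abs(z))
      flag <- flag & p < significance_gate
    }
  }
  structure(h$snp_ids[!flag], removed = h$snp_ids[flag])
}

#' Run the full six-rule instrument-selection sequence
#'
#' Applies, in order: exposure p-value threshold (1), outcome-association
#' exclusion (2), LD clumping (3, skipped with no LD matrix — SNPs are then
#' treated as independent), MR-PRESSO iterative outlier removal (4, via
#' [mr_presso()]; needs >= 4 SNPs), per-SNP weak-instrument exclusion and
#' the set-level F-statistic (5), and Steiger filtering (6). Every candidate
#' receives exactly one selection fate.
#'
#' @param exposure,outcome [summary_dataset()]s.
#' @param ld optional [ld_matrix()].
#' @param config a [selection_config()].
#' @param seed integer seed for the MR-PRESSO simulations.
#' @param palindromic_policy passed to [harmonize()].
#' @return List with `kept` (snp ids), `fates` (data.frame snp / fate /
#'   detail), `h` (final harmonized set or `NULL`), `f_stat` (set-level
#'   F-statistic list or `NULL`) and `presso` (the [mr_presso()] report when
#'   run).
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               config = selection_config(), seed = 1,
                               palindromic_policy = "drop") {
  fates <- data.frame(snp = character(0), fate = character(0), detail = character(0))
  note <- function(snps, fate, detail = "") {
    if (length(snps)) fates <<- rbind(fates, data.frame(snp = snps, fate = fate, detail = detail))
  }
  empty <- function() list(kept = character(0), fates = fates, h = NULL,
                           f_stat = NULL, presso = NULL)

  cand <- suppressWarnings(filter_by_pvalue(exposure, config$p_exposure_threshold))
  note(setdiff(exposure$snp, cand), "fail_pthresh",
       sprintf("exposure p >= %g", config$p_exposure_threshold))
  if (!length(cand)) return(empty())

  cand2 <- exclude_outcome_associated(cand, outcome, config$p_outcome_exclude)
  note(attr(cand2, "removed"), "fail_outcome_assoc",
       sprintf("outcome p < %g", config$p_outcome_exclude))
  cand <- as.character(cand2)
  if (!length(cand)) return(empty())

  if (!is.null(ld)) {
    cand3 <- clump(cand[cand %in% ld$snp_ids], exposure, ld,
                   config$clump_r2, config$clump_window_kb)
    rem <- attr(cand3, "removed")
    if (nrow(rem)) note(rem$snp, "clumped_away", paste("index:", rem$index_snp))
    cand <- as.character(cand3)
  }
  if (!length(cand)) return(empty())

  h <- tryCatch(harmonize(exposure, outcome, snp_ids = cand,
                          palindromic_policy = palindromic_policy),
                error = function(e) NULL)
  if (is.null(h)) { note(cand, "harmonize_dropped", "not harmonizable"); return(empty()) }
  note(h$palindromic_dropped, "harmonize_dropped", "palindromic (strand-ambiguous)")
  if (nrow(h$excluded)) note(h$excluded$snp, "harmonize_dropped", h$excluded$reason)

  presso <- NULL
  if (length(h$snp_ids) >= 4) {
    presso <- mr_presso(h, n_sim = config$presso_nsim, alpha = config$presso_alpha,
                        seed = seed)
    if (length(presso$removed)) {
      note(presso$removed, "presso_outlier", "MR-PRESSO iterative removal")
      h <- subset_harmonized(h, setdiff(h$snp_ids, presso$removed))
    }
  }

  # rule 5: per-SNP weak-instrument exclusion (k = 1 form of the F formula),
  # then the set-level F on the survivors.
  r2 <- r2_per_snp(h$beta_exposure, h$eaf)
  f_snp <- r2 * (h$n_exposure - 2) / (1 - r2)
  weak <- f_snp < config$f_min
  note(h$snp_ids[weak], "weak_instrument", sprintf("per-SNP F < %g", config$f_min))
  if (all(weak)) return(empty())
  h <- subset_harmonized(h, which(!weak))

  if (config$steiger_enabled) {
    kept_st <- steiger_filter(h, significance_gate = config$steiger_gate)
    note(attr(kept_st, "removed"), "steiger_removed", "r2 outcome > r2 exposure")
    if (!length(kept_st)) return(empty())
    h <- subset_harmonized(h, as.character(kept_st))
  }

  f_stat <- compute_f_statistic(h$snp_ids, exposure, n = h$n_exposure)
  if (f_stat$f < config$f_min)
    attr(f_stat, "weak_set") <- TRUE
  note(h$snp_ids, "kept", "")
  list(kept = h$snp_ids, fates = fates, h = h, f_stat = f_stat, presso = presso)
}
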