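# Benjamini-Hochberg FDR and the two-tier significance classification.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (sort ascending, `q_i = p_i m / i`, enforce
#' monotonicity from the largest down, cap at 1), returned in input order.
#' Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param pvals numeric vector of p-values in (0, 1]; empty in, empty out.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stopf("bh_adjust: p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Assign significance tiers within FDR strata
#'
#' BH adjustment is applied independently within each stratum (by default
#' the trait-category-by-outcome grouping). Tiers: `"significant"` when the
#' adjusted value (FDR) is below `fdr_sig` (default 0.1); `"suggestive"`
#' when the raw p is below `p_sug` (default 0.05) but the FDR is not;
#' `"null"` otherwise.
#'
#' @param pvals raw p-values.
#' @param strata character vector of stratum keys (recycled if length 1;
#'   use a single value for pooled correction).
#' @param fdr_sig,p_sug tier thresholds.
#' @return data.frame with `pval`, `fdr_q`, `tier`, `stratum` in input order.
#' @export
assign_tiers <- function(pvals, strata = "all", fdr_sig = 0.1, p_sug = 0.05) {
  if (!length(pvals)) return(data.frame(pval = numeric(0), fdr_q = numeric(0),
                                        tier = character(0), stratum = character(0)))
  strata <- rep_len(as.character(strata), length(pvals))
  q <- numeric(length(pvals))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    q[idx] <- bh_adjust(pvals[idx])
  }
  tier <- ifelse(q < fdr_sig, "significant",
                 ifelse(pvals < p_sug, "suggestive", "null"))
  data.frame(pval = pvals, fdr_q = q, tier = tier, stratum = strata)
}
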