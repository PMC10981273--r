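---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization estimates the causal effect of an
exposure X on an outcome Y from two non-overlapping GWAS. For SNP j, let
β_Xj and β_Yj be the true per-allele associations with X and Y, estimated
by β̂_Xj ~ N(β_Xj, σ²_Xj) and β̂_Yj ~ N(β_Yj, σ²_Yj). Under the
instrumental-variable assumptions (the SNP associates with X, is
independent of confounders, and affects Y only through X),
β_Yj = θ β_Xj, and every estimator in this package is a way of pooling the
per-SNP ratios β̂_Yj / β̂_Xj that trades efficiency against robustness to
violations of the third assumption (horizontal pleiotropy: a direct SNP
effect α_j on Y).

The mediation extension adds a mediator M with exposure→mediator effect
β_A and mediator→outcome effect β_B conditional on X. The total effect
decomposes as θ_total = θ_direct + β_A β_B; the package estimates β_A by
univariable MR, β_B by multivariable IVW (regressing β̂_Y jointly on the
exposure's and the mediator's β̂ columns), and reports
mediation effect = β_A β_B, direct effect = total − mediation, and
proportion = 100 · mediation / total.

## Estimators

- **Wald ratio** (1 SNP): θ̂ = β̂_Y/β̂_X, SE = σ_Y/|β̂_X| (first-order
  delta; exposure uncertainty ignored, the usual convention).
- **IVW**: weighted origin regression with weights 1/σ²_Yj. Fixed-effects
  SE is √(1/Σ w β̂²_X); the random-effects model inflates it by the
  multiplicative overdispersion factor √(max(1, Q/(k−1))) — floored at 1
  so random-effects SEs can never undercut fixed-effects ones. The `auto`
  rule uses random effects when Cochran's Q has p < 0.05.
- **Maximum likelihood**: the joint normal model with latent true
  instrument effects ξ_j profiles to the one-dimensional objective
  ½ Σ (β̂_Yj − θ β̂_Xj)²/(σ²_Yj + θ²σ²_Xj), minimised by Brent search
  started at the IVW estimate (a 500-iteration cap; non-convergence is an
  error carrying the last iterate); the SE comes from the numerical
  curvature of the profile. As σ_X → 0 it collapses to fixed-effects IVW,
  which the tests assert.
- **MR-Egger**: weighted regression with a free intercept after flipping
  each (β̂_X, β̂_Y) pair so β̂_X ≥ 0. The slope is consistent under
  InSIDE (instrument strength independent of direct effects); the
  intercept estimates the mean directional pleiotropic effect. SEs follow
  the weighted-least-squares convention (scaled by the residual σ̂), and
  p-values use the exact t reference with k − 2 degrees of freedom: with
  50 instruments the normal reference inflates the intercept test's
  type-I error to ≈ 5.6%, and the calibration experiment below checks the
  5% level. Confidence intervals stay on the package-wide normal
  convention.
- **Weighted median**: per-SNP ratios ordered ascending with normalized
  inverse-variance weights w_j = β̂²_Xj/σ²_Yj; cumulative weight
  standardized as (cumsum(w) − w/2)/Σw; the estimate interpolates
  linearly to 0.5, and an exact 0.5 boundary returns the ratio at that
  boundary (a tie rule the literature leaves to code). SEs by seeded
  parametric bootstrap (resampling β̂ from their sampling normals).
- **Weighted mode**: normal-kernel weighted density of the ratios with
  bandwidth `bandwidth_factor × 0.9 s k^(−1/5)`, where s is the
  weighted-MAD scale (falling back to the weighted SD, then to the
  highest-weight ratio, as the scale degenerates); the estimate is the
  density argmax refined by golden-section search. Identical ratios short-
  circuit to that ratio with SE 0.

On noiseless proportional data every estimator returns θ to 1e-6, which
the suite asserts.

## Instrument selection

Six rules run in sequence, each SNP receiving exactly one fate:

1. exposure association below a strict threshold (default locus-wide
   1e-5; 5e-8 for large-GWAS exposures such as anthropometric traits in
   reverse analyses);
2. exclusion of SNPs associated with the outcome (p < 0.05, strict);
3. greedy LD clumping: candidates visited in ascending exposure p-value
   (lexicographic SNP-id tie-break, making the output invariant to input
   order), a SNP removed when within the window of a kept SNP on the same
   chromosome with r² at or above the threshold. Presets r² < 0.001 /
   10,000 kb (default) and r² < 0.01 / 500 kb; windows are center-to-center
   kilobases on 1-based positions;
4. iterative MR-PRESSO outlier removal (below) — architecturally executed
   by the sensitivity machinery and fed back, since it needs outcome data
   and an MR fit, but behaviourally identical to running it as rule 4;
5. weak-instrument exclusion: per-SNP F = r²(n − 2)/(1 − r²) with
   r² = 2·EAF(1−EAF)β̂² on a variance-1 trait scale, dropping SNPs with
   F < 10, then the set-level F = R²(n − k − 1)/(k(1 − R²)) for
   reporting. EAF is therefore required; its absence is an error rather
   than a silent fallback;
6. Steiger filtering: remove SNPs explaining more outcome than exposure
   variance (optionally gated on the Steiger z-test; the default is the
   blunt point comparison).

Rule 2 deserves a warning. Excluding outcome-associated SNPs removes
precisely the strongest instruments whenever a real causal effect exists,
biasing the total effect toward zero and — because survivors are selected
for small outcome betas — distorting the Egger intercept at strong
effects. The rule is implemented exactly as specified (before clumping),
and the per-SNP fate table makes its cost visible; analyses of strongly
causal traits should consider raising `p_outcome_exclude`.

## Sensitivity battery

- **Cochran's Q** with first-order weights β̂²_X/σ²_Y and a χ²(k−1)
  reference. Under a null causal effect the statistic is exactly
  calibrated; with θ ≠ 0 the first-order weights ignore the θ²σ²_X term
  and Q is intrinsically overdispersed — a property of the statistic, not
  a defect, which is why the type-I calibration runs under the null.
- **MR-PRESSO**: observed statistic RSS = Σ w_j (β̂_Yj − θ̂_(−j)β̂_Xj)²
  with leave-one-out IVW predictions; the null distribution simulates
  β̂*_X ~ N(β̂_X, σ²_X), β̂*_Y ~ N(θ̂_(−j)β̂_X, σ²_Y) `n_sim` times
  (default 1000; p-values carry the +1 correction so they are never 0).
  The per-SNP outlier test compares each weighted residual with its
  simulated counterparts, Bonferroni-adjusted by k. Removal sorts SNPs
  ascending by outlier p and deletes one at a time, recomputing the
  global test, until global p > 0.05 or fewer than 4 SNPs remain (the
  leave-one-out fit needs 3); exhaustion sets `unresolved_pleiotropy`
  rather than guessing. The distortion test compares the pre/post-removal
  IVW shift against random same-size removals and is advisory only. The
  whole report is bit-reproducible under a fixed seed via counter-based
  seed splitting.
- **Leave-one-out** IVW (auto effects model) per excluded SNP.
- **Steiger direction**: total instrument variance explained in exposure
  versus outcome, with a z-test on the difference of Fisher-transformed
  implied correlations; equal totals count as no evidence of reversal
  (p = 1).

A pair advances to mediation only when IVW p < 0.05, Q p ≥ 0.05, Egger
intercept p ≥ 0.05 and MR-PRESSO global p > 0.05 — the stated screening
gate, with each threshold exposed in configuration.

## Multiple testing and evidence tiers

Benjamini–Hochberg adjustment (via `stats::p.adjust`, validated against a
brute-force step-up implementation on 1000 random vectors) is applied
within trait-category × outcome strata by default — the grouping implied
by correcting blood-cell and immune-cell panels separately — with a pooled
option. FDR < 0.1 is significant; p < 0.05 with FDR ≥ 0.1 suggestive.

For mediation, the delta-method SE of β_A β_B uses zero covariance
between the two steps (non-overlapping cohorts; a documented limitation
when samples overlap). The proportion CI is a first-order delta on the
ratio treating numerator and denominator as independent, and is suppressed
whenever the mediation CI spans zero — in that case the sign of a
proportion bound would be meaningless. Evidence is "strong" when the
triangle (all three nominal MR tests significant) holds and the mediation
CI excludes zero, "potential" when only the triangle holds.

## The synthetic generator

`simulate_summary_stats()` draws, per SNP: EAF ~ U(0.05, 0.95); true
exposure effects b_j ~ N(0, σ_b²) for instruments and 0 for null SNPs;
mediator effects β_A b_j (plus d_j ~ N(0, σ_b²) for mediator-specific
instruments); outcome effects θ_direct b_j + β_B(β_A b_j + d_j) + α_j,
with pleiotropic α_j zero for valid SNPs and N(μ_α, sd²) for the invalid
fraction — oriented relative to the exposure-increasing allele, so
"directional" means a non-zero mean in the orientation MR-Egger uses.
Reverse-causal SNPs carry a direct outcome effect and no exposure effect.
Standard errors follow the variance-1 closed form 1/√(2 n EAF(1−EAF)) for
continuous traits (and the same form as a log-OR approximation for binary
ones); observed betas add independent per-trait noise, reflecting the
non-overlapping-sample design. All randomness descends from one integer
seed through Lehmer-style stream splitting, so each dataset is
independently reproducible.

Two design choices were genuinely open:

- **Mediator-specific instruments.** With only exposure instruments, the
  mediator's beta column is β_A times the exposure's in truth, and the
  multivariable design is identified only by estimation noise. Real
  mediators (metabolites, cell counts) have their own GWAS hits, so the
  generator includes SNPs acting directly on the mediator; these identify
  the conditional β_B.
- **Effect-size scale.** The default σ_b = 0.03 at the default sample
  sizes (18,340 / 8,299 / 700,000 — the scale of microbiota, metabolite
  and anthropometric consortia) yields instrument F-statistics straddling
  the F = 10 threshold, exercising the weak-instrument rule.

What the generator does **not** emulate: realistic LD (only block-diagonal
toy matrices via `attach_block_ld()`), winner's-curse from discovery in
the same sample, sample overlap between cohorts, case-control
ascertainment, population stratification, or non-normal effect-size
distributions. Passing calibration therefore demonstrates correctness of
the estimators and diagnostics under the two-sample model's own
assumptions, not robustness to everything real data can do.

## Validation experiments and problem sizes

The calibration functions (`calib_*`) fix the experimental conditions:

- IVW bias: 200 replicates, 50 valid instruments, n = 50,000 per trait,
  σ_b = 0.1, true θ_total = 0.3; |mean bias| < 0.01.
- Type-I error: 500 null replicates (all causal effects zero); Cochran's
  Q and the Egger intercept each within 2 Monte-Carlo SEs of 5%.
- MR-PRESSO: 100 replicates, 20 instruments, one injected 10·SE outlier;
  the outlier has the smallest outlier p and is removed first in ≥ 95% of
  replicates, removal restores global p > 0.05, and clean replicates pass
  the global test ≥ 90% of the time (n_sim = 1000).
- Steiger: 20 replicates of 40 reverse-causal SNPs at σ_b = 0.03,
  n = 50,000, candidates selected on the *outcome* p-values — the
  discovery route that admits reverse-causal SNPs — with ≥ 90% removed.
- Mediation recovery: 200 replicates at (θ_direct = 0.1, β_A = 0.5,
  β_B = 0.4); mean estimated proportion within 3 Monte-Carlo SEs of
  100·β_Aβ_B/θ_total = 66.7%.

The calibration experiments deliberately run in a strong-instrument
regime (σ_b = 0.1, per-SNP F ≫ 10): IVW on noisily measured exposure
betas suffers regression dilution of order θ·σ²_X/(σ_b² + σ²_X), so a
bias bound of 0.01 presupposes strong instruments, and the experiments
measure estimator behaviour rather than the (known, documented)
weak-instrument attenuation. They also bypass the selection pipeline and
use the generator's known instrument ids — ground truth is the point of
simulation, and rule 2 above would otherwise inject its own distortion
into what is meant to be a calibration of the estimators.

## Numerical and degenerate-input choices

- P-values are clamped away from exact 0 at the smallest normal double;
  datasets validate se > 0, p ∈ (0, 1], alleles in {A, C, G, T}.
- Harmonization: sign-flip when the outcome lists alleles in the opposite
  order (frequency complemented); palindromic A/T and C/G SNPs are
  dropped by default, or kept when both frequencies fall on the same side
  of 0.5 outside [0.42, 0.58]; irreconcilable pairs are excluded with a
  reason code; the operation is idempotent and never changes an effect
  magnitude.
- Zero exposure betas make ratios undefined: the Wald ratio errors, while
  multi-SNP estimators and Q exclude the SNP with a warning.
- Exact-fit regressions (residual σ̂ = 0) report SE 0 with p collapsing
  to 0 or 1 by the point estimate.
- Ties in clumping and MR-PRESSO removal order break lexicographically by
  SNP id; all orderings in reports are deterministic.
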