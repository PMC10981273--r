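# mrmediate

Two-sample Mendelian randomization (MR) and two-step mediation analysis
from GWAS summary statistics, in R.

MR treats genetic variants as randomized instruments for an exposure: if a
variant affects the outcome only through the exposure, the ratio of its
outcome and exposure associations estimates the causal effect free of
classical confounding. `mrmediate` implements the full workflow that
studies of the gut microbiome, circulating metabolites, blood/immune cells,
inflammatory cytokines and anthropometric outcomes use, and extends it to
mediation: how much of a microbial taxon's effect on obesity flows through
a metabolite, a cell count, or a cytokine?

It is aimed at statistical geneticists and epidemiologists who want a
scriptable, fully seeded pipeline whose every stage can be exercised
against synthetic data with known ground truth — no consortium downloads
required.

## What it computes

For harmonized per-SNP effect pairs (β̂\_Xj, β̂\_Yj) with standard errors
(σ\_Xj, σ\_Yj):

- **Wald ratio** (single instrument): θ̂ = β̂\_Y / β̂\_X.
- **IVW**: weighted regression of β̂\_Y on β̂\_X through the origin,
  weights 1/σ²\_Yj; fixed-effects SE √(1/Σ w β̂²\_X), random-effects SE
  inflated by √(max(1, Q/(k−1))), chosen automatically by Cochran's Q.
- **Maximum likelihood**: profile likelihood of the linear model with
  latent true instrument effects, objective Σ (β̂\_Y − θβ̂\_X)² / (σ²\_Y +
  θ²σ²\_X).
- **MR-Egger**: weighted regression with free intercept after orienting
  β̂\_X ≥ 0; the intercept tests directional pleiotropy.
- **Weighted median / weighted mode**: interpolated 50th weighted
  percentile, and kernel-density argmax, of the per-SNP ratios; bootstrap
  SEs.
- **Instrument selection**: exposure p-threshold (1e-5 locus-wide or 5e-8
  genome-wide), exclusion of outcome-associated SNPs (p < 0.05), greedy LD
  clumping (r² < 0.001 / 10,000 kb or r² < 0.01 / 500 kb), iterative
  MR-PRESSO outlier removal, F-statistic screening
  (F = R²(n − k − 1) / (k(1 − R²)), per-SNP R² = 2·EAF(1−EAF)β²), and
  Steiger directionality filtering — each SNP gets an audit fate.
- **Sensitivity**: Cochran's Q, Egger intercept, full MR-PRESSO (global
  RSS test, per-SNP outlier test, removal trail, distortion test),
  leave-one-out, Steiger direction.
- **FDR tiering**: Benjamini–Hochberg within trait-category × outcome
  strata; FDR < 0.1 is significant, p < 0.05 with FDR ≥ 0.1 suggestive.
- **Mediation**: with β\_A the exposure→mediator effect and β\_B the
  mediator→outcome effect conditional on the exposure (multivariable IVW),
  mediation effect = β\_A·β\_B with delta-method SE
  √(β\_B²σ\_A² + β\_A²σ\_B²), direct effect = total − mediation,
  proportion = 100·mediation/total, and a strong/potential evidence tier.

## Worked example

Simulate a three-trait system (exposure → mediator → outcome) with known
truth — total effect θ = 0.04, of which β\_A·β\_B = 0.02 (50%) is mediated
— then run the forward MR and the two-step mediation:

```r
library(mrmediate)

truth <- simulation_truth(m_instruments = 50, m_mediator_instruments = 50,
                          theta_direct = 0.02, beta_a = 0.2, beta_b = 0.1,
                          sigma_b = 0.1, n_exp = 50000, n_med = 50000,
                          n_out = 50000, seed = 5)
study <- simulate_summary_stats(truth)

pair <- mr_analyze(study$exposure, study$outcome, seed = 2)
pair
#> <pair_result> exposure -> outcome: 31 instruments, primary p = 0.00275, advance = TRUE
pair$estimates$ivw
#> <mr_estimate> ivw_fixed: beta = 0.03494 (95% CI 0.01207, 0.05781), se = 0.01167, p = 0.00275, nSNP = 31

med <- run_mediation(study, seed = 2)
med
#> <mediation_result> exposure -> mediator -> outcome
#>   total 0.0349 | direct 0.0260 | mediation 0.0090 (0.0033, 0.0147), p = 0.002009
#>   proportion 25.65% (2.27%, 49.04%) | evidence: strong
```

Reading the output: 31 of the 50 instruments survive the six selection
rules (the audit trail is in `pair$fates`); the IVW estimate 0.035 is
within sampling error of the true total effect 0.04 and the pair passes
the no-heterogeneity / no-pleiotropy gate (`advance = TRUE`). The
mediation decomposition attributes 0.0090 of the total to the mediator
path — the identity total = direct + mediation holds exactly — with a CI
excluding zero, hence "strong" evidence. The estimated 26% proportion is
below the generative 50% mainly because the outcome-association exclusion
rule trims instruments (see the vignette's discussion of that rule).

A command-line wrapper with `simulate`, `select`, `mr`, `sensitivity`,
`mediate` and `run` subcommands lives at `inst/cli/mrmediate.R`:

```sh
Rscript inst/cli/mrmediate.R simulate --seed 1 --m 50 --out-dir sim
Rscript inst/cli/mrmediate.R mediate --study-dir sim --seed 1 --out-dir med
```

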