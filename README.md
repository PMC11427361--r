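# mrpath

Two-sample Mendelian randomization (MR) with sensitivity diagnostics,
Bayesian model averaging, and two-step mediation — from GWAS summary
statistics only.

## The problem

Observational associations between the gut microbiome, immune status and
disease (here, nasal, gallbladder, colon and gastric polyps) are confounded
by diet, lifestyle and reverse causation. MR sidesteps this by using
genetic variants as instruments: a SNP that shifts the abundance of a
microbial taxon is randomized at conception, so its association with the
outcome reflects the causal path — provided the instrument assumptions
hold. `mrpath` is for analysts who have per-SNP association statistics
(beta, standard error, p, alleles, allele frequency) for exposures,
candidate mediators and outcomes from non-overlapping GWAS, and want the
full inference chain with its assumption checks, not just a point
estimate.

## What it computes

For harmonized per-SNP effects (β_Xj, β_Yj) with standard errors, the
per-SNP Wald ratio is θ_j = β_Yj/β_Xj and the package provides:

- **IVW (random effects):** θ̂ = Σw_jθ_j / Σw_j with w_j = β_Xj²/se_Yj²,
  standard error 1/√Σw_j inflated by max(1, √(Q/(J−1)));
- **MR-Egger:** weighted regression β_Y = α + θβ_X, slope as causal
  estimate, intercept α as directional-pleiotropy test (t, J−2 df);
- **weighted median** (ratio at cumulative weight 0.5) and **simple /
  weighted mode** (kernel-density mode of the ratios), bootstrap SEs;
- **diagnostics:** Cochran's Q = Σw_j(θ_j − θ̂)², the Egger intercept,
  the three-step MR-PRESSO global/outlier/distortion procedure, and the
  Steiger directionality test r²(X) vs r²(Y);
- **MR-BMA:** posterior over subsets of candidate risk factors under an
  inverse-variance-weighted regression likelihood with a normal prior
  (variance 0.5) on standardized effects and Bernoulli(0.1) inclusion
  prior; per-candidate marginal inclusion probability (MIP),
  model-averaged causal effect (MACE) and permutation p;
- **mediation:** indirect effect β₁β₂, proportion mediated
  100·β₁β₂/β₃, and sign-consistency screening of
  exposure→mediator→outcome pathways;
- **instrument selection** (p < 1e-5, 500 kb / r² 0.1 greedy clumping,
  F = (β/se)² > 10, confounder blacklist), **harmonization** with
  palindrome handling, **BH-FDR**, a **synthetic-data generator** with
  known ground truth, and a study orchestrator (`run_study()`).

## Worked example

Simulate a microbiome-like exposure → immune-trait mediator → polyp chain
with a true total effect of 0.35 and 25% of it mediated, then run the full
univariate battery and the mediation decomposition:

```r
library(mrpath)

sim  <- simulate_triplet(sim_config(seed = 11))
legs <- triplet_instruments(sim)

estimate_all(legs$exp_out, seed = 1)
#>            method n_snp      beta         se         pval       or   ci_low  ci_high
#> 1          ivw_re    10 0.3711695 0.02070510 7.327567e-72 1.449429 1.391786 1.509459
#> 2           egger    10 0.3619142 0.02024982 9.841445e-08 1.436076 1.380195 1.494219
#> 3 weighted_median    10 0.3690247 0.02310508 2.016182e-57 1.446323 1.382286 1.513327
#> 4     simple_mode    10 0.4256546 0.20947683 4.215477e-02 1.530592 1.015194 2.307649
#> 5   weighted_mode    10 0.3658521 0.02406467 3.384372e-52 1.441742 1.375319 1.511374

sensitivity_report(legs$exp_out, n_sim = 1000, seed = 1)
#> Q=4.378 (df=9, p=0.885); Egger intercept p=0.519; PRESSO global p=0.875; Steiger correct=TRUE
```

All five estimators agree near the true log-odds ratio 0.35 (OR ≈ 1.45 per
unit of exposure), and the diagnostics are clean: no heterogeneity
(Q p = 0.885), no directional pleiotropy (intercept p = 0.519), no PRESSO
signal, and the Steiger test confirms the exposure→outcome direction. The
two-step decomposition recovers the mediated share:

```r
b1 <- ivw_random_effects(legs$exp_med)$beta  # exposure -> mediator
b2 <- ivw_random_effects(legs$med_out)$beta  # mediator -> outcome
b3 <- ivw_random_effects(legs$exp_out)$beta  # total effect
screen_pathways(data.frame(
  exposure_id = "taxon", mediator_id = "immune_trait", outcome_id = "polyp",
  beta1 = b1, beta2 = b2, beta3 = b3))$pathways
#>       beta1     beta2     beta3   indirect proportion_pct sign_consistent
#> 1 0.2587431 0.3623363 0.3711695 0.09375203       25.25855            TRUE
```

The estimated proportion mediated, 25.3%, matches the generative 25%. The
packaged worked-example table of 30 published microbiome→immune→polyp
pathways screens to 16 sign-consistent pathways (6 nasal / 1 gallbladder /
2 colon / 7 gastric):

```r
screen_pathways(mediation_examples())
#> Mediation screen: 30 pathways, 16 sign-consistent
#>       Colon polyp Gallbladder polyp     Gastric polyp       Nasal polyp
#>                 2                 1                 7                 6
```

A thin CLI over the same functions lives at `inst/cli/mrpath.R`
(verbs `simulate`, `screen`, `bma`, `mediate`, `all`, YAML config).

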