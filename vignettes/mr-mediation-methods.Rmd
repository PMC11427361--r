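---
title: "Methods: two-sample MR, sensitivity diagnostics, model averaging and mediation"
author: "mrpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, sensitivity diagnostics, model averaging and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The analysis the package implements

`mrpath` implements a genetic causal-inference workflow for questions of the
form *does exposure X (for example, the abundance of a gut microbial taxon)
causally affect outcome Y (for example, a polyp diagnosis), and is part of
that effect transmitted through mediator M (for example, an immune-cell
trait)?* — using only GWAS summary statistics. The workflow is:

1. **Instrument selection.** For each exposure, SNPs associated at
   p < 1e-5 are LD-clumped (500 kb window, r² > 0.1 pruned greedily by
   ascending p-value), filtered for instrument strength (F = (β/se)² > 10)
   and purged of SNPs on a user-supplied confounder blacklist (e.g. smoking
   and alcohol loci).
2. **Harmonization.** Outcome statistics are aligned to the exposure's
   effect allele, resolving allele swaps (negate β, complement the
   frequency) and strand flips, and dropping palindromic SNPs whose allele
   frequency cannot disambiguate the strand.
3. **Univariate MR.** Five estimators on the per-SNP Wald ratios
   θ_j = β_Yj/β_Xj: random-effects IVW (the primary estimate), MR-Egger,
   weighted median, and simple/weighted mode; Wald ratio when only one
   instrument survives.
4. **Sensitivity battery.** Cochran's Q, the MR-Egger intercept, the
   three-step MR-PRESSO residual-sum-of-squares procedure, and the Steiger
   directionality test.
5. **Prioritization.** Candidates that are nominally significant and free
   of heterogeneity/pleiotropy enter multivariable MR by Bayesian model
   averaging within their panel category; candidates are ranked by marginal
   inclusion probability (MIP), flagged as important when MIP > 0.1, with
   model-averaged causal effects (MACE) and permutation p-values.
6. **Two-step mediation.** Univariate IVW estimates of
   exposure→mediator (β₁), mediator→outcome (β₂) and exposure→outcome (β₃)
   are combined into the indirect effect β₁β₂, the proportion mediated
   100·β₁β₂/β₃, and a sign-consistency flag (β₁β₂ and β₃ nonzero and
   same-signed).

All estimation is authored in the package; standard statistical machinery
(weighted least squares, chi-square and t reference distributions, BH
adjustment via `stats::p.adjust`) comes from base R.

## Estimators and their assumptions

**IVW.** The inverse-variance-weighted estimate is the weighted regression
of β_Y on β_X through the origin with weights 1/se_Y², equivalently
Σw_jθ_j/Σw_j with w_j = β_Xj²/se_Yj². It is consistent when every
instrument is valid (no horizontal pleiotropy). The random-effects flavour
multiplies the fixed-effect standard error by max(1, sqrt(Q/(J−1))) — an
overdispersion scale floored at one, so balanced pleiotropy widens the
interval but can never shrink it below the fixed-effect interval. Inference
is normal-theory.

A design note on the floor: because the scale is floored at 1, the
random-effects IVW test is mildly conservative under the null at small
instrument counts (about 3.8% rejection at the 5% level with 10–20
instruments, approaching 4.4% by J = 80 in our operating-characteristic
simulations). The calibration checks in the test suite therefore run at
J = 50, a realistic count for traits with many suggestive loci, where the
realized rate sits well inside the nominal band.

**MR-Egger.** Weighted regression of β_Y on β_X *with* an intercept, after
orienting all β_X non-negative (flipping β_Y in tandem). Under the InSIDE
assumption the slope is a consistent causal estimate even with directional
pleiotropy, and the intercept estimates the average pleiotropic effect.
Inference uses the standard weighted-least-squares t statistics with J − 2
degrees of freedom and *no* dispersion floor: the plain t-test is exactly
calibrated under the null (we measured 4.8–5.1% empirical size at J = 10–15
over 20,000 replicates), whereas flooring the residual dispersion at 1 —
a convention some implementations apply — deflates the size to 1.6–3.2%.
A numerically perfect fit (zero residual dispersion) is resolved by the
size of the estimate: exact proportionality gives intercept p = 1.

**Weighted median.** Order the ratios, accumulate normalized
inverse-variance weights, and interpolate the ratio at cumulative weight
0.5. Consistent when valid instruments carry at least half the weight.
The standard error is a seeded parametric bootstrap (default 1000 draws of
β_X and β_Y from their sampling normals).

**Mode estimators.** The mode of a normal-kernel density over the ratios,
bandwidth φ·1.06·s·J^(−1/5) with s the (weighted) standard deviation of the
ratios and φ = 1 by default; equal weights for the simple mode,
inverse-variance weights for the weighted mode. Consistent under ZEMPA
(the largest group of instruments is valid). The mode is located by a dense
grid scan refined with golden-section search; degenerate dispersions return
the weighted mean of the (identical) ratios.

**Dispatch.** One instrument → Wald ratio only (first-order delta-method
standard error se_Y/|β_X|; a second-order variant is available behind a
flag). Two instruments → IVW only. Three or more → all five estimators.

## Sensitivity diagnostics

**Cochran's Q** at the IVW estimate, referred to chi-square with J − 1 df;
Q is minimized at the fixed-effect IVW estimate, which the tests assert on
an ε-grid.

**MR-PRESSO.** (1) *Global test*: the observed weighted residual sum of
squares of leave-one-out IVW predictions is ranked within `n_sim`
(default 1000) parametric simulations of pleiotropy-free instrument sets;
p is the +1-smoothed exceedance rank, so its granularity is 1/(n_sim + 1)
and it is bit-reproducible for a fixed seed. (2) *Outlier test*: per-SNP
observed squared residuals against their simulated distributions,
Bonferroni-adjusted across instruments, flagged at adjusted p < 0.05.
(3) *Distortion test*: the relative change of the IVW estimate after
outlier removal, ranked against the change under removal of equally many
random SNPs. Flagging every instrument is a degenerate-correction error.

**Steiger directionality.** Per-trait instrument r² is approximated from
the test statistics, r² = Σ t_j²/(t_j² + n − 2), and the causal direction
is called correct when the instruments explain more variance in the
exposure than in the outcome. Because the exposure and outcome samples do
not overlap in a two-sample design, the p-value is a two-sample Fisher-z
test on the pooled correlations with the respective sample sizes. For
binary outcomes the same approximation is applied on the log-odds scale —
a documented approximation: the "variance explained" of a liability is not
identified from log-odds statistics, but only the comparison of the two r²
values matters here and the exposure side dominates by orders of magnitude
in realistic settings.

**Exclusion rule.** Before model averaging, an exposure is excluded when
Q p < 0.05, the Egger intercept p < 0.05, or the PRESSO global p < 0.05.
Diagnostics that cannot be computed (too few instruments) do not trigger
the gate.

## Multivariable MR by Bayesian model averaging

With J instruments and d candidate exposures, each subset γ of candidates
is an inverse-variance-weighted regression model of β_Y on the included
β_X columns. After scaling rows by 1/se_Y and columns to unit root mean
square ("standardized effects"), the marginal likelihood under an
independent normal prior of variance σ² = 0.5 on standardized effects has
the closed form of a zero-mean Gaussian with covariance I + σ²Z_γZ_γᵀ,
evaluated via the Woodbury identity and a Cholesky factorization of the
k × k inner matrix. The model prior is independent Bernoulli(0.1)
inclusion per candidate. Posteriors are normalized over all 2^d models
(enumerated exhaustively up to d = 16) or over the distinct models visited
by a seeded Metropolis-style shotgun search (add/delete/swap proposals,
10,000 proposals by default) for larger panels; exhaustive and stochastic
posteriors agree to within 0.02 MIP on d = 8 test problems.

Per candidate we report the **MIP** (the summed posterior probability of
all models containing it), the **MACE** (the posterior-weighted average of
its conditional ridge-posterior effect, zero in models that exclude it),
and a **permutation p-value**: the +1-smoothed exceedance rank of the
observed MIP among MIPs recomputed on outcome-permuted data (minimum
attainable p = 1/(n_perm + 1)). Candidates are ranked by MIP with ties
broken by identifier; "important" means MIP strictly above 0.1. The
"prior probability 0.1 / prior variance 0.5 / 10,000 iterations" settings
are exposed as configuration keys with exactly those roles.

Two caveats the tests make explicit: MIPs are scale-invariant in the
outcome (common rescaling of β_Y and se_Y changes nothing), and the
permutation test loses resolution when the signal saturates (observed and
permuted MIPs both reach 1 when standard errors are tiny relative to the
effects; the permutation p is then conservative).

## Two-step mediation

The three path coefficients are estimated by separate univariate IVW fits.
The decomposition assumes effect homogeneity and no exposure–mediator
interaction, under which the total effect is β₃ = direct + β₁β₂ and the
proportion mediated is 100·β₁β₂/β₃. The proportion is invariant under
recoding of the mediator (flipping β₁ and β₂ together) or of the exposure
(flipping β₁ and β₃ together) and antisymmetric in the sign of β₃ alone;
it can legitimately be negative ("inconsistent mediation") when the
indirect and total effects oppose — such pathways are flagged not
sign-consistent, as are pathways with a zero product or zero total effect.
No standard error is attached to the decomposition by default; a
first-order delta-method standard error for β₁β₂ is available
(`indirect_effect_se`).

The package ships a 30-row worked-example table of published
gut-microbiome → immune-trait → polyp pathways (`mediation_examples()`)
with path effects printed to three decimals. Recomputing the mediator
effect from the printed β₁, β₂ reproduces the printed products to within
1e-3 (the combined rounding bound) on every row, and the recomputed
proportions match the printed ones to within 0.1 percentage points on 28
of 30 rows; the two exceptions (0.114 and 0.124 pp) are exactly the rows
where propagating the ±0.0005 input rounding through β₁β₂/β₃ exceeds
0.1 pp, i.e. the published table was evidently computed from unrounded
effects. The screening of this table yields 16 sign-consistent pathways:
6 nasal, 1 gallbladder, 2 colon, 7 gastric.

## The synthetic-data generator

`simulate_triplet()` generates two-sample summary statistics for an
exposure → mediator → outcome chain with known truth. Per-SNP true
exposure effects γ_j are scaled so the instruments explain a configured
fraction of exposure variance; the mediator inherits β₁γ_j and has its own
instruments δ_k scaled to their variance share; the outcome receives
θγ_j + β₂δ_k plus configurable pleiotropy α_j (none, balanced,
directional, or injected outliers at 10× the median absolute outcome
effect). Observed statistics add independent panel noise at the analytic
standard error 1/sqrt(2·maf·(1−maf)·n), with the case-control variance
inflation 1/(v(1−v)) for a binary outcome of case fraction v on the
log-odds scale. Identical configurations and seeds are bit-reproducible.

Default conditions mirror the data the pipeline targets: exposure GWAS
n = 18,340 (microbiome-consortium scale), mediator GWAS n = 3,757
(a small immune-trait cohort), outcome GWAS n = 290,000 with 2.1% cases;
MAF uniform on (0.1, 0.4); β₁ = 0.25, β₂ = 0.35, θ = 0.35, hence a true
mediated proportion of 25%. Instrument strength defaults to the *upper*
(immune-trait-like) end of the realistic range — 10 exposure instruments
explaining 40% of variance (mean F ≈ 750) and 3 mediator instruments
explaining 80% (plausible for immune traits, whose small-cohort GWAS
exhibit single-SNP F statistics in the thousands) — because two-sample IVW
carries an O(1/F) weak-instrument attenuation: at microbiota-like strength
(F of 15–90) the attenuation of the point estimate, although only about
1–2%, is *larger* than the Monte-Carlo standard error of a 500-replicate
recovery study, so exact-recovery checks are only meaningful in the
strong-instrument regime. Users simulating microbiota-like exposures
should expect, and will observe, that small attenuation.

What the generator does *not* emulate: real LD (the LD matrix is
block-diagonal with configurable within-block r²), realistic allele
frequency spectra, sample overlap, population stratification, or
winner's-curse selection of instruments. Passing recovery tests on this
generator therefore demonstrates correctness of the estimators and
plumbing, not robustness to those real-data complications.

## Multiplicity and the screening gates

Primary (IVW/Wald) p-values are BH-adjusted within each outcome block —
the FDR family is a genuinely open design choice; adjusting within
outcome × exposure-class blocks is the configurable default documented
here because it matches how the screens are reported. Downstream stages
(model averaging, mediation) are gated on the *raw* p < 0.05 call plus
clean diagnostics, reflecting the common practice of carrying nominally
significant hits forward while reporting FDR-adjusted significance
separately.

## Numerical choices and problem sizes

- Clumping ties (equal p) break by chromosome, position, then SNP id, so
  results are independent of input order.
- Palindromic ambiguity window: drop when min(eaf, 1−eaf) > 0.42 on either
  side, or when eaf is missing on either side; the window is configurable.
- Bootstrap and simulation seeds are mandatory arguments; every stochastic
  result in a report is reproducible from the run metadata.
- The test suite's simulation studies use 100–1000 replicates per claim
  (1000 for null calibration at J = 50; 500 for chain-parameter recovery;
  200 for outlier-detection and directionality power; 100 panels for
  model-averaging rank recovery), sizes at which each check's Monte-Carlo
  error is well inside the asserted bands; the full suite runs in a few
  minutes on one core.

## Known limitations

- No correlated-instrument IVW, MR-RAPS, or debiased IVW; no proxy-SNP
  lookup, liftover, or reference-panel clumping.
- The Steiger r² approximation on the log-odds scale is heuristic (see
  above).
- MR-PRESSO's distortion test conditions on the flagged outlier set; its
  p-value inherits the usual post-selection caveat.
- The mediation decomposition is the product method only; no
  multivariable-adjusted direct effects.
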