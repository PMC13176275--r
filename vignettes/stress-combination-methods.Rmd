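---
title: "Methods: bootstrap additivity analysis of combined abiotic stresses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bootstrap additivity analysis of combined abiotic stresses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresscombo)
```

## The problem

Crops in the field rarely face one stress at a time. When warming coincides
with drought or salinity, the joint effect on growth and resource use need
not equal the sum of the single-stress effects: stresses can amplify each
other (synergism) or partially mask each other (antagonism). `stresscombo`
implements the inferential chain for a two-stressor pot experiment laid out
as a split plot — temperature regimes on main plots (whole benches or
chambers), water regimes on subplots (pots within them) — from raw per-pot
measurements through trait derivation, estimation statistics, an additivity
test, univariate ANOVA, and multivariate treatment separation.

## Trait derivation

Nine traits are computed per pot from six raw measurements:

* shoot and root dry weight (g), and water consumption = total water
  applied (L);
* **WUE** = biomass / water (g L⁻¹) and **NUE** = biomass / N uptake
  (g g⁻¹);
* **N uptake** `N_t` = biomass × N concentration (mg g⁻¹ → g);
* **¹⁵N fertilizer recovery** by isotope dilution: the plant's ¹⁵N excess
  over natural abundance (0.3663 atom%) relative to the fertilizer's excess,
  times `N_t`; percent recovery divides by the amount of fertilizer per pot
  `f`;
* **carbon-isotope discrimination**
  Δ = (δ_air − δ_plant) / (1 + δ_plant/1000), with δ_air = −8.15‰.

Two accounting choices are genuinely open and are exposed as switches:

* **Biomass basis.** N uptake, WUE and NUE use shoot + root biomass by
  default, because the N and isotope analyses are performed on a composite
  shoot+root sample; `biomass = "shoot"` restricts them to shoots.
* **The recovery denominator `f`.** Percent recovery is conventionally per
  unit fertilizer *N*; the default `f` = 0.0403 g is the N mass in 190 mg of
  ammonium sulfate (0.212 g N per g). Users who express recovery per unit
  fertilizer mass can set `fert_amount_g` (and `fert_basis`) accordingly.
  Only percent recovery is affected; the recovered amount is not.

## Effect sizes: Δ-mean with BCa intervals

Treatment effects are reported as unpaired mean differences with
bias-corrected and accelerated bootstrap 95% CIs (5 000 resamples by
default). The contrast plan compares each single stress against the
untreated control (WW) and each combined stress against its single-stress
baseline. Implementation conventions, fixed for bit-reproducibility:

* each group is resampled independently at its own size (pots are the
  resampling unit; main-plot structure is ignored at this stage);
* the bias correction `z0` is the normal quantile of the proportion of
  bootstrap statistics below the observed value, ties counted half;
* the acceleration `a` is the jackknife skewness over all observations of
  both groups;
* endpoints use the (B+1)α order-statistic convention (R quantile type 6),
  matching the standard bootstrap references; adjusted levels falling
  outside the achievable range are clamped to the extreme order statistic
  and flagged.

**Known limitation.** BCa intervals are first-order accurate: with 10 pots
per group their empirical coverage for a Gaussian mean difference is about
92% rather than the nominal 95% (our own simulations, 4 000 experiments at
1 000 resamples, agree with the `boot` package's implementation to
Monte-Carlo error). Users needing exact small-sample coverage should read
the intervals as slightly liberal.

## The Additivity Index

For stressors *i* and *j*, with all effect sizes measured against the same
control,

AI = ES_ij − (ES_i + ES_j).

The point estimate reduces to `mean(ij) + mean(ww) − mean(i) − mean(j)`.
Each bootstrap iteration resamples the four groups jointly and recomputes
AI, preserving the index's sampling distribution rather than combining
separately stored contrast bootstraps. The CI is bias-corrected percentile
(z0 only) by default: a jackknife acceleration for a four-group functional
is costly and not uniquely defined, but a grouped leave-one-pot-out variant
is available (`method = "bca"`). The p-value is the two-sided resampling tail
probability with a +1 correction, so p > 0 always.

Classification: **additive** when the CI contains 0. Otherwise the sign of
AI is compared with the sign of S = ES_i + ES_j, the expected additive
effect: equal signs mean the combination overshoots the additive expectation
(**synergistic**), opposite signs mean it falls short (**antagonistic**).
This is the natural formalization of "stronger/weaker than expected" and is
recorded in the output so users can re-derive either convention. Heatmap
cells report 100·AI/mean(WW), with cells at a zero control mean flagged
undefined rather than infinite, and significance marked at p < 0.05 per
cell. No multiplicity correction is applied across cells; the 36 tests are
exploratory, and users needing family-wise control can feed the p-values to
`p.adjust`.

A subtlety of the split-plot layout: in a balanced design the main-plot
random effects cancel exactly in the AI point estimate (WW and the water
stress at ambient temperature share main plots with opposite signs, as do
the warmed pairs), while the independent-group bootstrap still counts that
variance. With non-negligible main-plot variance the index's CI is therefore
conservative. Our calibration simulations use independent pots
(σ_mainplot = 0), where the nominal 5% false-positive rate is the right
benchmark.

## Split-plot ANOVA

The classical completely-randomized split-plot decomposition: temperature is
tested against the among-main-plots-within-temperature mean square, water
and temperature×water against the subplot residual. Replicates are treated
as nested within temperature (main-plot error df = t(r−1), e.g. 27 for
3×3×10); a blocked variant with a replicate main effect is available
(`blocked = TRUE`) for layouts where replicates were physical blocks.
Unbalanced data are rejected outright rather than approximated — Type II/III
decompositions for unbalanced split plots are out of scope. Diagnostics are
Shapiro–Wilk on the subplot residuals and Brown–Forsythe (median-centered
Levene) across the nine treatment groups; transformations (log, sqrt) are
applied only on request, never silently, and both fits are reported when a
refit is triggered.

## Canonical discriminant analysis

CDA solves the generalized eigenproblem of the between-group scatter against
the pooled within-group scatter. Conventions:

* traits enter unstandardized — the within-scatter whitening makes the
  analysis invariant to affine rescaling of individual traits, which the
  test suite verifies;
* canonical variates are scaled to unit pooled within-group variance;
* structure loadings are total-sample correlations between traits and
  scores;
* the sign of each variate is fixed so its largest-|loading| trait loads
  positively, making seeded runs comparable;
* pots missing any trait are dropped listwise with a reported count.

Pairwise Mahalanobis squared distances use the covariance pooled across all
groups (df ν = N − g) and the Hotelling T²-to-F transformation
F = (ν − p + 1)/(νp) · T² on (p, ν − p + 1) df; with two groups this is the
classical two-sample Hotelling test, an identity the tests check against an
independent computation.

## The synthetic-data generator

The generator exists so that every downstream stage has known ground truth.
One `trait_model` per raw measurement generates

y = μ + αᵢ + βⱼ + (αβ)ᵢⱼ + mainplot(σ_m) + ε(σ_e),

with sum-to-zero main effects and an interaction matrix with zero marginal
sums — so "additive" has an exact meaning: the interaction matrix *is* the
departure from additivity, and a planted (αβ) of zero makes the Additivity
Index's null exactly true. Cell means can be supplied directly
(`trait_model_from_cell_means()`), which is how the defaults are encoded.

Default scenario (3 temperature × 3 water regimes × 10 replicates = 90
pots): the cell means of the six raw measurements emulate a vegetative-stage
maize pot trial under warming combined with water or salt stress — well-
watered shoot biomass ≈ 1.24 g per pot with a ~20% reduction under water
stress and ~49% under salt stress; root growth mildly stimulated by drought
but halved by salt; water consumption reduced by drought and salt but
increased by warming; tissue N concentration elevated under salt; plant ¹⁵N
abundance around 0.8–1.3 atom% (recovery of the order of 10% of fertilizer
N); δ¹³C near −14‰ (Δ ≈ 5.9‰, a typical C4 window). Residual SDs are sized
so that 95% CIs of 10-replicate mean differences have widths comparable to
what such trials report (e.g. σ ≈ 0.12 g for shoot); the main-plot SD is set
at roughly a third of the residual SD, reflecting benches under a common
lamp being more alike than pots within them.

Choices and caveats, flagged explicitly:

* **Gaussian errors are an assumption.** Nothing in the design of pot
  experiments guarantees normal main-plot or residual variation; the
  generator is a statistical emulation, not a growth model (no temperature
  time series, soil-moisture dynamics, or allometry). Passing tests
  demonstrate correctness of the *statistics* under the assumed error model,
  not robustness to real-data pathologies (skewness, outliers,
  heteroscedasticity beyond what Levene catches).
* Positivity of masses and water, and the physical range of atom% ¹⁵N
  (natural abundance to fertilizer enrichment), are enforced by rejection
  sampling (up to 1 000 redraws per value) rather than truncation, to avoid
  biasing cell means; an unreachable bound is an error, not a silent fix.
* Measurements are independent across traits by default; real traits are
  correlated (biomass drives both WUE and N uptake mechanically through the
  derivation step, which the trait module reproduces, but raw-measurement
  correlations are not simulated).
* Every trait draws from an RNG substream named by `(seed, trait)`, so
  adding a measurement never perturbs the others; all pipeline stages use
  substreams derived from one master seed, making results independent of
  execution order and byte-reproducible.

## Numerical and reproducibility choices

* Problem sizes used in the validation suite: 10⁴ random inputs for the
  trait formulas against direct arithmetic; 1 000 simulated experiments ×
  1 000 resamples per coverage setting; 500 additive experiments at 1 000
  resamples for the type-I rate; 150 experiments per point of the power
  curve; 2 000 null experiments for the three split-plot F tests; exact
  oracle comparisons at 1e-10 (ANOVA projections) and 1e-8 (CDA scatter
  algebra).
* Bootstrap seeds: every contrast and additivity cell derives its own
  substream from `(seed, trait, contrast)` via a 31-bit string hash
  (`derive_seed()`), exact in double arithmetic on all platforms.
* Degenerate inputs: constant groups yield degenerate CIs at the point
  estimate; a singular pooled covariance aborts the CDA with the condition
  number; an unbalanced ANOVA aborts listing the problem, and missing trait
  values abort listing the pots.
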