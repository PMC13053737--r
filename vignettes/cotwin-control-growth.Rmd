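---
title: "Methods: co-twin control growth-curve analysis of functional aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-twin control growth-curve analysis of functional aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the measurement
constructions, the simulator that supplies synthetic study conditions, the
numerical choices, and the design decisions taken where more than one
reasonable implementation existed.  It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The growth model

Functional aging is modeled as a two-piece linear spline in age.  The age
basis centers observed age at 75 years and scales it per decade,
`t = (age − 75) / 10`, split into `s1 = min(t, 0)` and `s2 = max(t, 0)`.
The intercept is therefore expected functioning at age 75, slope 1 the
rate of change per decade *before* 75 and slope 2 the rate *after* 75.
The knot at 75 reflects the empirical acceleration of functional decline
around that age; the per-decade scaling keeps slope estimates on an
interpretable scale and conditions the optimization.

The outcome for visit $j$ of person $i$ in pair $p$ is

$$y_{pij} = \beta_0 + \beta_1 s1_{pij} + \beta_2 s2_{pij}
  + \beta_{sex}\,\mathrm{female}_{pi} + (\text{SES terms})
  + u_p + u_{1p} s1 + u_{2p} s2
  + v_{pi} + v_{1pi} s1 + v_{2pi} s2 + \varepsilon_{pij},$$

with random effects at two levels — pair and person-within-pair — so that
"phenotypic" (whole-sample) models are corrected for twin clustering.
SES covariates can load on any subset of {intercept, slope 1, slope 2};
in co-twin models the covariate is replaced by its between-pair mean and
within-pair deviation.

**Assumptions.** Gaussian random effects and residuals; missing outcome
rows missing at random (dropped listwise, together with rows missing a
required covariate); linearity of the SES effects; homogeneous residual
variance.  Singleton twins (incomplete pairs) are retained in phenotypic
models with pair-level and person-level effects of their own — their two
variance components simply add in the marginal covariance — and are
removed by `complete_pairs()` for co-twin models, which require both
members.

**Estimation.** The exact marginal Gaussian likelihood is maximized with
`lme4::lmer` under `REML = FALSE`.  ML (not REML) is the default because
the pipeline's inferential workhorse is the likelihood ratio test between
fixed-effect-nested models, which is invalid under REML; a REML flag
exists for variance reporting.  Covariances are kept positive
semi-definite by the Cholesky-factor parameterization.  Wald p-values use
a normal reference: with thousands of person-occasions the t degrees of
freedom are large enough that the distinction is immaterial, and no
finite-sample df recipe is uniquely defensible here.

**Random-structure fallback.** The requested structure (`full`:
unstructured 3×3 at both levels) falls back automatically to `diagonal`
and then `intercept` on failure to converge, and the structure actually
used is recorded in the fit object.  Boundary (singular) fits are
accepted — a variance legitimately estimated at zero is not an error.
The `pair` option (unstructured at pair level, intercept at person level)
suits designs with few waves per person, where person-level slope
variances are weakly identified.

**Likelihood ratio test.** `lrt()` computes $2(\ell_1 - \ell_0)$ with df
equal to the difference in the number of estimated parameters, requiring
ML fits on identical observations.  A negative statistic within numerical
tolerance is clamped to zero; beyond tolerance it is reported as a
convergence failure of the full model rather than silently truncated.
Identical fits give statistic 0, df 0 and p = 1.

## Measurement constructions

**Functional Aging Index.** Four components: sex-adjusted grip strength,
height²-adjusted peak expiratory flow, gait, and self-reported sensory
function.  The standardization is estimated once on a declared baseline
reference (each person's earliest visit by default) and then frozen; it
can be serialized to YAML so follow-up waves are scored against baseline
parameters.  Components are z-scored against baseline means/SDs and
oriented so higher = poorer (grip and peak flow reversed by default; gait
is treated as time-to-walk, unreversed — a `reverse` flag flips it for
speed-coded data).  Decisions taken where the construction was open:

* vision and hearing are each z-scored and averaged into *one* sensory
  component before composite formation, keeping the component count at
  four;
* the composite is the unweighted mean of available component z-scores,
  tolerating missingness down to `min_components = 3` (below that the
  index is missing, not an error);
* the composite is re-standardized against the *baseline composite
  distribution* before the T-map `50 + 10z`, so "mean 50, SD 10" refers
  to the composite itself on the baseline reference — exactly, which the
  acceptance suite checks at 1e-8;
* baselines are pooled across studies by default, with a per-study option
  (the within-sample convention is only documented for the strain score).

**Financial strain.** A single-factor model is fitted by maximum
likelihood (`stats::factanal`) to the four standardized items, loadings
sign-fixed so their sum is positive.  Uniquenesses are floored at 0.005;
a floor hit is flagged as a Heywood case.  Items with essentially zero
inter-correlation are flagged as a weak structure — ML then returns a
boundary solution rather than all-zero loadings, so the flag is driven by
the correlation matrix, not the loadings.  Scoring uses regression
(Thomson) factor scores; for respondents with missing items the score is
computed from the observed-item submodel, which equals the conditional
expectation of the factor given the observed items under the fitted
Gaussian model (verified against a Monte-Carlo conditioning oracle in the
tests).  Scores are mapped to mean 50 / SD 10 within each declared sample
(`study_label`); with one sample the whole table is the sample.
Consortium-level loadings are not available to this package, so loadings
are estimated from the data at hand or supplied frozen via YAML.

## The co-twin control machinery

`decompose_between_within()` is exact arithmetic: pair mean and deviation,
with within values summing to zero in every pair and
`between + within` reconstructing each member.  `fit_cotwin_models()`
refits the growth model on complete pairs, in the full sample and per
zygosity stratum.  Strata with fewer than `min_pairs` (default 10)
complete pairs are skipped with a warning — an opposite-sex-only cohort
yields a DZ-only report.  Parental SEI enters only where configured,
following the convention of conditioning covariate inclusion on the
phenotypic results (in the motivating analyses it mattered for the strain
model only).

**MZ-vs-DZ comparison.** The default statistic combines the stratified
estimates, $z = (\hat\gamma_{w,DZ} - \hat\gamma_{w,MZ}) /
\sqrt{SE_{MZ}^2 + SE_{DZ}^2}$, treating the strata as independent (they
partition the sample).  A joint-model variant (one fit on MZ + DZ with a
zygosity-by-within interaction) is available and agrees with the
SE-combination within about 10% on balanced simulated data.  Published
analyses of this design have reported a t statistic with an unusual df
that cannot be reconstructed from stratified estimates alone; this
package reports the large-sample z and makes no claim to reproduce such a
t.

**Confounding classification.** The verbal attenuation logic is made
reproducible by numeric thresholds (`confounding_thresholds()`):
attenuation ratios $r_g = \hat\gamma_{w,g}/\hat\gamma_{b,g}$, ratio-keep
0.7, ratio-drop 0.3, equality band 0.2, Wald significance at
$\alpha = 0.05$, one-sided comparison threshold z = 1.64.  The rule, in
order: (i) within significant in both strata with both ratios ≥ 0.7 →
consistent causal; (ii) within non-significant in MZ, comparison
favoring DZ or $r_{MZ} < 0.3$, and $r_{DZ} \ge 0.7$ → genetic
confounding; (iii) within non-significant in both strata with
$|r_{MZ} - r_{DZ}| < 0.2$ → shared-environment confounding; otherwise
indeterminate, with a low-power flag when the within SEs exceed the full
between-pair estimate.  The comparison z is aligned with the sign of the
full-sample between effect and the ratios are scale-free, so the verdict
is invariant to a sign reversal of the SES variable.

Two consequences of the significance conditions are worth stating
plainly.  First, a true direct effect too small for the stratified tests
lands in *indeterminate with low power*, not in *consistent causal* —
on printed occupation-style estimates whose MZ within effect is
non-significant, that is the returned verdict, matching the cautious
reading ("suggestive rather than definitive") such patterns deserve.
Second, per-scenario recovery of a generating shared-environment scenario
is capped near $0.95^2 \approx 0.90$ at *any* sample size, because the
rule demands non-significance in two independent strata whose true within
effects are exactly zero.  The recovery guarantee is therefore evaluated
*pooled* over the scenario grid, where the expected rate is ~0.95.

**Descriptive statistics.** Twin correlations are double-entered Pearson
(intraclass) correlations — each pair contributes both orderings, making
the estimate exchangeable in member order.  Falconer components are
$a^2 = 2(r_{MZ} - r_{DZ})$, $c^2 = r_{MZ} - a^2$, $e^2 = 1 - r_{MZ}$,
truncated to the admissible region and renormalized with a boundary flag
when the raw solution is inadmissible (the raw values are retained).
`compare_correlations()` is the standard Fisher z comparison of
independent correlations, treating twins as independent observations, as
such descriptive tables conventionally do.

## The simulator and its oracle

`simulate_cohort()` generates, per pair: additive-genetic latents A
correlated 1 (MZ) or 0.5 (DZ), one shared-environment latent C,
independent unique latents E, all unit variance; standardized SES
$aA + cC + eE$ with loadings from the configured ACE components; person
growth parameters combining fixed effects, cross-paths ($\delta$ from
SES, $\kappa_A$ from A, $\kappa_C$ from C, on the intercept and
optionally slope 1), and pair- plus person-level random effects; and
wave-wise outcomes on the spline basis with residual noise.  Everything
is reproducible from the seed.

Default configuration — these are the emulated study conditions, chosen
once: 142 MZ and 371 DZ pairs with about half the DZ pairs opposite-sex;
SES with an ISEI-like scale (mean 36.3, SD 19.2) and ACE structure solved
from twin correlations 0.53 / 0.29; intercept 47.3, slopes 4.4 and 9.9
per decade (post-knot about twice pre-knot), female offset 2.9, on a
T-score metric; baseline ages uniform on 42–93; up to 8 waves spaced
uniformly 2–4 years (follow-up up to ~27 years); 12% independent per-wave
dropout after baseline.  Random-effect SDs (pair 5/1.5/2, person 5/1.5/2,
residual 5 in T units) are not published quantities; they were chosen so
that total intercept variance sits near the T-scale variance of 100 with
a realistic familial share.  The simulator can also emit the four raw
biomarkers as noisy affine images of the latent outcome (so the scoring
pipeline can be exercised end-to-end) and an ISCED-like 0–8 ordinal
obtained by thresholding SES at the deciles of its configured marginal.

What the generator does **not** emulate: outcome-dependent (mortality)
dropout — dropout is independent by default, and the unique-environment
component deliberately conflates measurement error with true unique
environment, as the design itself does.  There is no dominance component,
no assortative mating, no gene–environment interaction, and no
sex-specific cross-paths (sex-specific confounding scenarios are
constructed in the tests from the emitted latent truth table).  Passing
tests on these synthetic cohorts therefore demonstrates the estimators'
correctness under the design's own model class, not robustness to
selective attrition or measurement-model misspecification in real
registry data.

`oracle_coefficients()` gives the closed-form population between/within
coefficients implied by any configuration (per SD of latent SES):
within-MZ $= \delta$ always; within-DZ
$= \delta + \kappa_A a / (a^2 + 2e^2)$; between-MZ
$= \delta + (\kappa_A a + \kappa_C c)/(a^2 + c^2 + e^2/2)$; between-DZ
$= \delta + (0.75\,\kappa_A a + \kappa_C c)/(0.75 a^2 + c^2 + e^2/2)$.
These formulas are the package's core correctness gate: empirical OLS
coefficients on large simulated cohorts must match them within
Monte-Carlo error.

**Scenario presets.** `scenario_config()` ships causal / genetic /
shared-environment scenarios at two effect sizes (paths of 2 or 1 T-units
per SES SD — comparable in standardized magnitude to published co-twin
SES effects on functional aging, e.g. 0.21 T-points per strain T-point
≈ 2.1 per SD), with ACE (0.2, 0.6, 0.2) and deliberately small
trajectory noise.  The presets are designed by analytic power calculation
from the oracle so that every non-capped condition of the decision rule
holds with probability near 1 at 2000 pairs per zygosity; what remains is
the irreducible significance cap discussed above.

## Problem sizes and seeds

Simulation experiments use these sizes, chosen for precision per unit
compute and stated here as the package's configuration of record:
fixed-effect recovery, 500 replicates of 1000 pairs × 4 waves with
intercept-level random effects (bias measured in units of the outcome SD;
Wald coverage pooled over the generating fixed effects, since the
[0.93, 0.97] band is sized for a single 500-replicate binomial check);
verdict recovery, 12 replicates per cell of the 3 × 2 scenario grid at
2000 pairs per zygosity, 2 waves; LRT null calibration, 1000 replicates
of 100 pairs × 2 waves; oracle agreement, 50,000 pairs per zygosity,
single wave at the knot age so the outcome is the person intercept
exactly; likelihood-oracle equivalence, 10-pair instances against a
multi-start Nelder-Mead dense-covariance optimizer.  `scripts/acceptance.R`
re-runs the same experiments at reduced replicate counts and derives all
sub-seeds from its single `--seed` argument through fixed offsets;
`run_pipeline()` uses the same one-seed-with-offsets rule and records it
in the provenance block.

## Known limitations

Wald-normal intervals ignore variance-parameter uncertainty and are
mildly anticonservative for person-level covariates at moderate cluster
counts.  The classifier's thresholds are conventions, not estimates;
verdicts near the thresholds deserve inspection of the evidence list
rather than consumption of the label alone.  Ordinal strain items are
treated as numeric (no polychoric factor model).  The ISCED/ISEI/SEI
codes are taken as given integers — no occupation or education text
harmonization is attempted.  Real registry data carry selection and
mortality processes the simulator does not generate; conclusions about
those require sensitivity analyses outside this package's scope.
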