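---
title: "Methods: comparative risk assessment of CKD burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative risk assessment of CKD burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery: the
attribution model and its assumptions, the standardization and trend layers,
the projection model, what the synthetic-cohort generator emulates (and what
it does not), and the numerical and design choices that were genuinely open.

## The comparative risk assessment framework

The package attributes prevalent CKD cases to seven modifiable risk factors —
systolic and diastolic blood pressure (SBP, DBP), body mass index (BMI),
current smoking, triglycerides (TG), HDL cholesterol and plasma glucose — by
comparing each factor's observed population distribution with a
*theoretical minimum risk exposure distribution* (TMRED): the counterfactual
exposure distribution conferring the lowest risk. The registry
(`ckd_risk_factors()`) carries, for each factor, the TMRED and a
meta-analytic relative risk (RR) with its 95% CI.

Two attribution formulas are used. For categorical exposures with category
shares $P_i$ and relative risks $RR_i$,

$$\mathrm{PAF} = \frac{\sum_i P_i (RR_i - 1)}{\sum_i P_i (RR_i - 1) + 1}.$$

For continuous exposures with population density $P_1(x)$, counterfactual
density $P_2(x)$ and maximum exposure level $m$,

$$\mathrm{PAF} =
  \frac{\int_0^m RR(x) P_1(x)\,dx - \int_0^m RR(x) P_2(x)\,dx}
       {\int_0^m RR(x) P_1(x)\,dx}.$$

Attributable cases are $\mathrm{PAF} \times \text{prevalence} \times
\text{population}$ (prevalence 10.8%, 95% CI 10.2–11.3%, over 846,662,309
adults by default). Factors are reported separately and never summed:
attributable cases of correlated factors overlap.

### Dose–response and its assumptions

Per-unit relative risks ("per 10 mm Hg", "per kg/m²") are compounded
log-linearly: $RR(x) = RR_\text{unit}^{(x - \mu_T)/u}$ above the TMRED mean
$\mu_T$. Linear compounding was rejected because it breaks multiplicativity
over increments ($RR(\mu_T + 2u)$ must equal $RR(\mu_T + u)^2$). Below the
TMRED mean the RR is floored at 1: the framework defines the TMRED as the
minimum-risk level, so no protective extrapolation is allowed. This makes
$RR(x)$ continuous, non-decreasing, and equal to 1 at the TMRED.

### The counterfactual integral

$P_2$ is a normal with the published TMRED mean and SD, truncated to
$[0, m]$ (exposures are physically non-negative; $m$ is the maximum observed
exposure, and both integrals use the same truncation for consistency). The
factual integral is evaluated *exactly* as the weighted mean of $RR(x_i)$
over the standardized empirical sample — not over a stratum mean, which
would understate the PAF by Jensen's inequality — and the counterfactual
integral by adaptive quadrature (`stats::integrate`, relative tolerance
1e-10; the region below $\mu_T$ contributes its probability mass exactly,
since $RR \equiv 1$ there). A PAF can be non-positive if the observed
distribution sits at or below the counterfactual; it is returned with a
warning rather than clamped.

### Smoking categories

The published current-smoking burden corresponds to a *current vs
not-current* contrast (RR 1.34): the headline PAF, the prevented-case
estimates and the 2031 projection are only mutually consistent under that
reading, so `ckd_risk_factors()` defaults to the two-category mode. The
three-category mode (`smoking = "three"`), which assigns the ever-smoking RR
1.27 to former smokers, is available; it yields a larger and much flatter
PAF, because quitting then moves people from RR 1.34 to RR 1.27 rather than
to the reference.

### Uncertainty propagation

The published inputs carry uncertainty but no propagation recipe, so the
package uses Monte Carlo (`burden_with_ci()`): each draw samples every
relative risk log-normally — $\log RR \sim N(\log RR_\text{point},
(\log RR_{hi} - \log RR_{lo})/3.92)$ — and the disease prevalence from a
normal on the logit scale matched to its CI, then recomputes the PAF and
case count. Intervals are 2.5/97.5 percentiles of 1,000 draws by default;
the point estimate always uses the point inputs. RR and prevalence draws are
independent (no correlation information exists), and exposure-sampling
uncertainty is not redrawn — the intervals reflect parameter uncertainty,
which dominates at the survey sizes involved.

## Standardization and trends

All population-level exposure summaries are directly standardized to a
census reference over the 16 joint strata (age 18–39/40–59/60–69/≥70 × sex ×
urban/rural), using age attained at each wave. The standardized mean is
$\sum_s W_s m_s$ with census shares $W_s$ and stratum sample means $m_s$;
its SE follows from independent stratum means. A stratum with census weight
but no observations is a hard error naming the stratum — silent
renormalization would quietly change the estimand. Missing exposure values
are dropped per factor and wave (complete case; the source analysis states
no imputation).

Secular trends (`trend_test()`) regress the exposure — or the
current-smoking indicator, a linear probability model matching the percent
scale of the published tables — on calendar year as a numeric ("scored")
regressor with covariate adjustment, and use cluster-robust (by person)
standard errors with $t_{G-1}$ reference. The original analysis used a SAS
general linear mixed model whose random-effects structure is not fully
specified; the fixed-effects-plus-clustering form is a documented
simplification, validated by simulation (type-I error within [0.03, 0.07]
at $\alpha = 0.05$ in the suite) rather than by matching published
p-values. Covariate-adjusted wave means (`adjusted_means()`) use
G-computation: average model predictions over the pooled covariate
distribution with the wave set to each value, so waves are compared at a
common covariate profile.

## Projection

Exposures are projected with a two-stage random-effects model per stratum
(`fit_stratum_trend()`), among participants observed in at least three
waves: stage one fits an OLS slope per individual; stage two pools the
slopes by inverse-variance weighting with a DerSimonian–Laird
between-individual variance. Two numerical choices matter here:

* **Pooled residual variance.** Individual fits have 1–3 residual degrees of
  freedom, and constant trajectories (a lifelong never-smoker's 0/1 series)
  report zero residual variance — under raw inverse-variance weighting they
  would receive infinite weight and collapse the pooled slope to zero. The
  sampling variance of each slope therefore uses the stratum-pooled residual
  variance divided by the individual's year spread. The pooling stage is
  cross-checked against `metafor::rma(method = "DL")` in the test suite.
* **Two-stage rather than full likelihood.** The two-stage estimator is
  fully specifiable, deterministic and testable; a full mixed model could be
  swapped in behind the same interface.

Projections anchor at the *last observed standardized value* (2011; 2009 for
blood factors), not the fitted intercept, so the projected series continues
the observed one. The overall projected mean is the census-weighted
combination of stratum slopes — identical, by linearity, to combining
stratum-level projections. Continuous factors project the full distribution
by a location shift (shape and variance preserved), because the continuous
PAF needs all of $P_1$ in 2031 and no information about shape change exists.
Smoking is projected on the prevalence scale, clipped to $[0, 1]$ (a
logit-scale option would never clip but the source's choice is unstated; the
linear scale is kept as default for transparency). Ages are *not* advanced
and the population is held at its 2010 structure — the acknowledged
convention of the source analysis, which overstates early-period burden and
understates future burden in an ageing population. Likewise the
attributable-case series applies the 2011 case total to all waves.

## The synthetic cohort

The generator (`simulate_cohort()`) emulates the statistical structure the
analysis relies on, not the survey's sampling design:

* **Individual-level trajectories.** Exposure = stratum baseline + stratum
  slope × years + person random intercept + person random slope × years +
  within-person noise, with the stratum taken at the attained age. Default
  spreads (SBP 10/0.15/8, DBP 7/0.10/5, BMI 2.5/0.04/1.0 for
  intercept/slope/noise SDs) give total cross-sectional SDs of roughly 15
  mm Hg, 9 mm Hg and 2.9 kg/m², realistic for adult populations.
* **Calibration.** Stratum baselines and slopes are built additively from
  the published sex, age-group and residence margins and recentred so the
  census-standardized adult means follow the published endpoints: SBP
  115→125 mm Hg, DBP 74→79 mm Hg, BMI 21.67→23.92 kg/m² over 1991–2011.
  Within-period wiggles of the published wave-specific values are *not*
  reproduced for continuous factors (the generator is linear in year);
  smoking does follow the published per-wave values.
* **Smoking.** Entry status is drawn from the per-sex never/former/current
  shares; current smokers may quit between waves (hazards chosen so
  prevalence tracks the published per-sex trajectories) and never re-start.
  The synthetic census male share is 0.4725 — the unique value under which
  the published sex-specific smoking margins and the published standardized
  overall path (33.7% → 26.5%) are simultaneously consistent; the joint
  census is otherwise a product of marginal shares (ages 45/37/11/7%,
  residence 50/50) over 846,662,309 adults.
* **Blood panel.** TG and glucose are log-normal and HDL-C normal
  (sex-specific), generated only in the 2009 wave, with location parameters
  solved from target threshold-exceedance fractions (TG>1.7: 25%,
  glucose>5.6: 3.8%, HDL low: 20.2% of men, 5.5% of women) — the exceedance
  levels implied by the published attributable fractions and the registry
  RRs.
* **Open cohort.** Per-wave retention 0.88 (the survey's reported response
  rate), with replenishing entrants drawn at all adult ages so the age
  structure stays stationary; ages advance deterministically between waves.
* **Covariates.** Province, education and occupation are exchangeable labels
  with no effect by default; a config switch adds an education effect with a
  drifting education distribution so covariate adjustment is testable.

What passing tests on this cohort do *not* show: fidelity to the survey's
cluster sampling, weights, item non-response, measurement error, or any
non-linear secular trend in the continuous factors. The per-wave panel sizes
used in the suite (700–6,000) and the acceptance script (12,000) are chosen
for statistical stability of the stratum estimates, with Monte-Carlo
tolerances set accordingly.

## Degenerate inputs and tie-breaks

* Zero generator noise reproduces stratum targets exactly; the projection
  estimator detects the all-noise-free case and returns exact slopes with
  zero variance components.
* Zero-width RR or prevalence CIs collapse the Monte-Carlo intervals onto
  the point estimate.
* Age-group boundaries are left-closed: 39 → 18–39, 40 → 40–59, 70 → ≥70;
  participants under 18 are rejected everywhere.
* DBP is capped 5 mm Hg below SBP in the generator (the joint tail where
  the independent draws would cross is ~0.3%).
* Proportions are clipped to [0, 1] after projection; projected current
  smoking is additionally capped at 1 − never.

## Known limitations

* The trend test is a working replacement for the original mixed model; its
  p-values are calibrated by simulation, not benchmarked against SAS output.
* The attributable-case series and projections inherit the fixed-population
  convention described above.
* Blood factors have one measurement wave, so their trends cannot be
  estimated — they are carried forward, and only the four longitudinal
  factors are projected.
* PAFs of correlated factors overlap; no joint (multiplicative or
  mediation-adjusted) attribution is attempted.
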