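# ckdburden

Comparative risk assessment (CRA) of modifiable risk factors for the chronic
kidney disease (CKD) case burden in the Chinese adult population, as an R
package. It is written for epidemiologists and biostatisticians who want a
tested, reproducible implementation of the full pipeline: census-standardized
exposure trajectories from an open longitudinal cohort, population-attributable
fractions (PAFs) against theoretical-minimum-risk exposure distributions
(TMREDs), attributable case counts with Monte-Carlo uncertainty, and a
two-stage random-effects projection of exposures and burden twenty years
forward.

Because the underlying survey microdata require registration, the package
ships a calibrated synthetic-cohort generator that emulates the open-cohort
structure (eight waves 1991–2011, entry and dropout, a single blood-panel
wave) and the published stratum trajectories, so every stage runs and is
testable end to end without any download.

## The model

For a categorical exposure with category shares `P_i` and relative risks
`RR_i` (reference category at 1), the attributable fraction is the Levin form

    PAF = Σ P_i (RR_i − 1) / ( Σ P_i (RR_i − 1) + 1 ).

For a continuous exposure with population distribution `P1(x)` and
counterfactual TMRED distribution `P2(x)` (a normal with the published TMRED
mean and SD, truncated to `[0, m]` with `m` the maximum observed exposure),

    PAF = ( ∫ RR(x) P1(x) dx − ∫ RR(x) P2(x) dx ) / ∫ RR(x) P1(x) dx,

where the dose–response is log-linear above the TMRED,
`RR(x) = RR_unit^((x − TMRED) / unit)`, floored at 1 below it. The factual
integral is evaluated exactly over the census-standardized empirical sample;
the counterfactual integral by adaptive quadrature. Attributable cases are
`PAF × prevalence × population`; uncertainty is propagated by resampling the
relative risks log-normally from their 95% CIs and the prevalence on the
logit scale.

Exposure distributions are directly standardized to the 2010 census
population over the 16 joint strata (age group 18–39/40–59/60–69/≥70 × sex ×
urban/rural). Secular trends use calendar year as a scored regressor with
cluster-robust errors by person; projections pool per-individual least-squares
slopes (participants with ≥3 waves) with a DerSimonian–Laird random-effects
stratum model.

## Worked example

```r
library(ckdburden)

cfg <- default_cohort_config(n_individuals = 6000)
survey <- simulate_cohort(cfg, seed = 7)
census <- generate_census(cfg)          # 846,662,309 adults in 16 strata

fit <- cra(survey, census, n_draws = 300, seed = 7)
print(fit)
```

```
Comparative risk assessment of CKD burden
  cohort: 48000 person-waves, 11053 individuals, waves 1991-2011
  CKD prevalence 10.8% (95% CI 10.2-11.3), population 846,662,309
  total CKD cases: 91.4 million
  attributable burden in 2011 (leading factors):
    smoking  PAF 7.9%, 7.2 million cases
    sbp      PAF 7.4%, 6.8 million cases
    tg       PAF 7.3%, 6.7 million cases
```

The total is prevalence × population (0.108 × 846,662,309 ≈ 91.4 million
cases). Each factor's PAF compares the standardized 2011 exposure
distribution with its TMRED counterfactual; multiplying by the case total
gives the attributable millions. `summary(fit)` adds the confidence
intervals and per-factor trend tests; `coef(fit)` returns the PAFs;
`predict(fit)` projects the burden to 2013–2031:

```r
proj <- predict(fit, years = c(2021, 2031), n_draws = 300)
proj[proj$year == 2031, c("factor", "exposure", "paf", "attributable")]
```

```
   factor    exposure        paf attributable
2     bmi  26.0864053 0.09089558      8311449
4     sbp 134.7820483 0.13285861     12148529
6     dbp  84.1216391 0.08453703      7730026
8 smoking   0.1799387 0.05765205      5271676
```

Mean SBP, projected to rise from about 125 to about 135 mm Hg by 2031,
raises its attributable burden; the continuing decline of current smoking
(to ~18% here) lowers its burden even as it remains a leading factor.
`run_pipeline()` executes simulate → standardize → attribute → project in
one call and writes the three report tables plus a JSON manifest, with
byte-identical output under a fixed seed.

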