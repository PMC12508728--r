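# hydromark

Dynamic hydration-response modelling of quantitative liver and spleen
MRI markers.

Quantitative MRI markers of the liver — T1 in particular — are promising
non-invasive tools for staging metabolic dysfunction-associated
steatotic liver disease (MASLD), but they respond to physiology as well
as to pathology: drinking an isotonic beverage transiently raises liver
and spleen T1 by amounts comparable to disease effects. `hydromark` is
an R package for scientists quantifying that confound. It models an
organ's T1 time course after drink ingestion as a first-order linear
time-invariant (LTI) system

τ·dy/dt + y = u(t),

driven by an idealised input u(t): a **rectangular pulse** for the liver
(fluid arrives from the gut through the portal vein as a prolonged
bolus, with gain k, onset delay Δ and duration δ) and a **trapezoid**
for the spleen (gradual systemic arrival; up-slope δ₁, flat top δ₂,
down-slope δ₃). The liver response is

y(t) = k(1 − e^−(t−Δ)/τ)u(t−Δ) − k(1 − e^−(t−Δ−δ)/τ)u(t−Δ−δ) + y₀,

and the spleen response is the corresponding superposition of four ramp
responses. The package provides:

* closed-form responses for step, rectangular and trapezoidal inputs,
  plus a fixed-step RK4 reference integrator (`ode_oracle()`) used to
  validate them to < 1e−4 ms;
* bounded multi-start Levenberg–Marquardt estimation of the dynamic
  parameters from longitudinal marker series (`fit_liver()`,
  `fit_spleen()`);
* a study-shaped synthetic cohort generator (`generate_cohort()`):
  6 participants × 3 drink volumes (0.5/1.0/1.5 L) × 8 markers
  (liver/spleen T1, T2\*, PDFF, ADC, stiffness, organ volumes) with
  marker-specific sampling cadences and gains calibrated to published
  group-level maximum changes;
* descriptive maximum-change statistics with paired t-tests
  (`max_change()`, `summarize_cohort()`);
* circular-ROI extraction from 2-D parametric maps (`roi_mean()`,
  NIfTI or CSV);
* linear mixed models relating fitted parameters to covariates
  (`fit_lmm()`, random intercept per participant, REML, Satterthwaite
  inference);
* an end-to-end pipeline (`run_pipeline()`) and a thin CLI
  (`inst/cli/hydromark.R`).

## A worked example

```r
library(hydromark)

# a study-shaped synthetic cohort with the default (published) dynamics
cohort <- generate_cohort(6, c(0.5, 1, 1.5), generator_config(), seed = 42)

# descriptive stage: signed maximum changes per marker and volume
t2 <- summarize_cohort(cohort, c("T1_liver", "T1_spleen"))
print(as.data.frame(t2[, c("marker", "volume_L", "abs_mean", "abs_sd",
                           "rel_mean_pct", "p_value")]), digits = 3)
#>      marker volume_L abs_mean abs_sd rel_mean_pct  p_value
#> 1  T1_liver      0.5     54.5  14.70         7.36 2.71e-04
#> 2  T1_liver      1.0     51.6   7.47         6.97 1.32e-05
#> 3  T1_liver      1.5     93.9  18.24        12.74 5.58e-05
#> 4 T1_spleen      0.5     37.1  16.89         2.85 3.00e-03
#> 5 T1_spleen      1.0     68.3  14.98         5.26 1.01e-04
#> 6 T1_spleen      1.5    172.1  33.36        13.25 5.52e-05
```

Mean maximum liver T1 change rises from ~55 ms at 0.5 L to ~94 ms at
1.5 L (the generating targets are 58/60/90 ms), spleen T1 from ~37 to
~172 ms (targets 45/70/150 ms); all T1 paired tests are significant,
as in the source study. Fitting one liver series recovers its dynamics:

```r
s <- cohort_series(cohort, "P01", 0.5, "T1_liver")
fit_liver(s)
#> <lti_fit> rectangular input, sse = 202.4, converged = TRUE
#> <lti_params> gain = 92.23, tau = 1855 s, delay = 675.5 s, baseline = 738.3
```

i.e. for this participant's 0.5 L session, a fitted water-uptake time
constant of ~31 min and an onset delay of ~11 min. Fifteen noisy points
only loosely pin the gain/time-constant pair for a single session
(this participant's generating values were k = 113 ms, τ = 2876 s,
Δ = 726 s); group-level means over the cohort are far tighter. The
full pipeline —

```r
run_pipeline("hydromark_out", pipeline_config(seed = 42))
```

— writes `cohort.csv`, `covariates.csv`, `fits.csv`, `table2.csv`
(maximum-change summary), `table3.csv` (group-mean fitted parameters),
`lmm.json` (covariate mixed models) and `run.log`, each stamped with
the package version, seed and configuration hash.

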