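---
title: "Methods: discrete-time hypoglycemia hazard modelling in ICU cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete-time hypoglycemia hazard modelling in ICU cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Hypoglycemia (blood glucose at or below 70 mg/dL, 3.9 mmol/L) is a feared
complication of glycemic control in intensive care, and body-mass index
(BMI) is a candidate modifier of its risk: heavier patients appear to
experience both less hypoglycemia and lower short-term mortality (the
"obesity paradox"). Quantifying that association from electronic health
records requires machinery that is surprisingly easy to get subtly wrong:
glucose is sampled irregularly (hours apart), exposure to insulin and
nutrition varies within a stay, and the outcome itself censors the data —
once a patient becomes hypoglycemic, everything afterwards is conditioned
on the event.

`glycohazard` implements that machinery as a tested, reusable pipeline:

1. **Glycemic statistics** per stay: hypoglycemia detection, episode
   construction, time-weighted average (TWA) glucose, coefficient of
   variation (CV), hypoglycemic load, monitoring frequency.
2. **Covariate engineering** at arbitrary query times: bounded
   last-observation-carried-forward (LOCF) imputation, shock flags,
   insulin/dextrose dose normalisation, hourly SOFA scores.
3. **A discrete-time hazard dataset**: one record per patient per 6-hour
   window, with the binary outcome H = "hypoglycemia in the next window"
   and censoring at the first event.
4. **Statistics**: a pooled logistic regression (odds ratios, Wald CIs,
   generalized variance-inflation factors, likelihood-ratio chi-square for
   BMI), percentile-bootstrap group summaries and two-sample tests.
5. **A synthetic ICU-cohort generator** with known ground-truth hazard
   coefficients, used for parameter-recovery and calibration testing.

# The discrete-time hazard model

Time is measured in hours from ICU admission, per stay. At feature times
$t = 6, 12, 18, \dots$ (while $t$ is before both discharge and the first
hypoglycemia onset) we assemble the covariate state at $t$ and ask
whether the first hypoglycemic measurement falls in the *outcome window*
$(t, t+6]$. If yes, the record gets $H = 1$ and the stay contributes no
further records; otherwise $H = 0$. A stay whose first onset precedes the
first feature time contributes nothing to the model (it still counts in
univariate analyses). Partial terminal windows before discharge are kept
with $H = 0$.

The pooled model is a plain logistic regression across all windows of all
stays,

$$\operatorname{logit} P(H_{it}=1) = \beta_0 + \beta^\top x_{it},$$

with the covariates binned exactly as reported in the clinical literature
this design follows:

| term | levels (referent first) |
|---|---|
| BMI group | [18.5,25), [0,18.5), [25,30), [30,35), [35,40), >=40 kg/m² |
| blood glucose | [70,108), [108,144), [144,180), >=180 mg/dL |
| insulin (max hourly dose, past 12 h) | 0, (0,2.5], (2.5,5], >5 u/h |
| blood lactate | [0,2), [2,5), >=5 mmol/L |
| shock | no (MAP >= 60 mmHg, no vasopressor) / yes |
| dextrose-10% equivalent rate | 0, (0,25), >=25 mL/h |
| parenteral / enteral nutrition, corticosteroids | absent / present |
| SOFA without cardiovascular component | continuous, 0–20 |
| database | site indicator, first site as referent |

Windows are half-open on the right: an onset exactly at a feature time
belongs to the *preceding* window, so every onset is attributable to
exactly one record. Repeated windows from the same patient are pooled
without cluster adjustment — matching the standard pooled discrete-time design; a future
clustered-SE option would change the CIs, not the point estimates.

# Glycemic statistics

**Episodes.** A hypoglycemic measurement opens an episode that
provisionally ends 6 h later; a further hypoglycemic measurement inside
the open episode extends it (new provisional end 6 h after that
measurement); a non-hypoglycemic measurement inside the open episode
closes it at its own time; otherwise the episode closes at the
provisional end, truncated at discharge. Two conventions are not forced
by the verbal rule and are fixed here: a terminating non-hypoglycemic
measurement closes the episode *at its own time* (not retroactively),
and a hypoglycemic measurement arriving exactly at the provisional end
starts a *new* episode. Both are measure-zero under continuous sampling;
the test suite's independent oracle (interval-union construction) uses
the same tie-breaks.

**TWA glucose** integrates the LOCF step function from the first
measurement to the end of the observation window and divides by the
elapsed time. LOCF (rather than trapezoidal) integration matches the
"time-weighted" convention of the glycemic-control literature, stays
well-defined with a single observation, and is exactly what an
hourly-grid EHR pipeline computes. The window ends at the earlier of
discharge and first hypoglycemia onset, so post-event treatment response
cannot contaminate the exposure summary.

**CV** is the unweighted percent coefficient of variation (sample SD /
mean) of the raw measurements. Whether published analyses of this kind exclude
post-onset measurements from the CV is not documented; both windows are
supported (`cv_window = "pre_onset"` default, `"full"` optional).
Hypoglycemic load and lowest glucose use the whole stay — on the
pre-onset window the load of a hypoglycemic patient would be zero by
construction.

# Covariate engineering

**Bounded LOCF.** Frequently measured variables (glucose, lactate, MAP)
are carried forward at most 24 h; daily labs (bilirubin, platelets,
creatinine, PaO2/FiO2, GCS) at most 48 h; beyond the horizon the
per-database median fills in (provenance is tracked as
observed/carried/median). The 48 h horizon is stated for liver function
tests in clinical EHR practice; it is extended here to all daily labs on the
grounds of identical sampling cadence. Medians are computed per database
(not pooled) since care patterns differ by site; a variable a site never
measures falls back to the pooled median. A never-observed GCS defaults
to 15 — the usual EHR convention that sedation-free patients with no
recorded GCS are neurologically intact — before any median fallback.

**Insulin dose** is the maximum over the hourly bins covering
$(t-12, t]$ of the infusion rate active in the bin plus bolus units
delivered in the bin. **Dextrose** is normalised to dextrose-10%
equivalents (rate × concentration/10); dextrose 5% is excluded by
convention (maintenance fluid, not a glycemic intervention). **Shock**
is MAP < 60 mmHg or any vasopressor. **SOFA** components use the
original consensus thresholds; because the minimal schema carries only a
generic vasopressor flag (no drug-specific doses), any vasopressor scores
the cardiovascular component at 2, the lowest catecholamine band. The
model uses the SOFA total *without* the cardiovascular component, which
would otherwise be collinear with the shock flag (the GVIF diagnostic
guards against residual collinearity).

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with known truth:

* **Sites.** Four site labels (`aumc`, `hirid`, `mimic`, `eicu`) with
  mixing proportions 8.5/12/9.5/70% (the multi-centre analog dominating,
  as in the real four-database setting); `eicu` has 10 hospitals with
  heterogeneous insulin practice so the hospital-prevalence filter has
  something to do. Per-site hazard intercept shifts default to the
  spread of the reported database odds ratios (1, 0.43, 0.92, 1.51).
* **Stays.** BMI groups with probabilities (3, 31, 34, 18, 7, 6)/99
  (a large teaching-hospital mix; the printed row sums to 99% from
  rounding, hence the normalisation), BMI uniform within group, height
  by sex, diabetes probability rising with BMI (10–40%), length of stay
  lognormal with mean 72 h (floored at 13 h so every stay has at least
  one window).
* **Glucose.** Measurement times follow a renewal process with mean gap
  4 h (gaps clipped to [0.5, 20] h — at least daily monitoring, so
  carry-forward never exhausts and imputation medians never enter the
  hazard path); values are AR(1) around a BMI-by-diabetes group mean
  (SD 30 mg/dL, lag coefficient 0.7), floored at 71 mg/dL. The floor
  means *every* hypoglycemic measurement is hazard-driven, which is what
  makes the ground-truth coefficients recoverable.
* **Hazard.** At each candidate window the covariates are computed and
  binned by the same code path the fitter uses
  (`window_feature_table()`), and $H$ is drawn from the logistic hazard
  with the configured coefficients; on an event a glucose value uniform
  in [40, 70] is inserted at a uniform time inside the window (clipped
  at discharge). Applying the hazard on the binned scale is a deliberate
  design decision: parameter-recovery tests then measure the estimator,
  not binning error. A `hazard_scale = "continuous"` switch applies a
  linear hazard on raw covariates instead, for misspecification studies.
* **Reference scenario.** BMI odds ratios (1.6, 1, 0.72, 0.65, 0.61,
  0.53) — monotone-decreasing, mirroring the reported direction — with a
  referent-cell per-window hazard of 2% (chosen once as realistic: it
  yields an overall per-stay hypoglycemia incidence near 14%, in the
  range reported for ICU cohorts). Treatments: insulin probability 80%
  when the latent glucose mean exceeds 150 mg/dL (15% otherwise), scaled
  by a per-hospital practice multiplier in [0.45, 1.25]; dextrose 5% of
  stays; PN/EN/steroids 8/35/12%; shock 25% of stays (vasopressor
  interval plus lower MAP). Mortality is logistic in BMI group and
  hypoglycemia occurrence (intercept 8%, hypoglycemia OR 2.5,
  BMI effects reproducing the obesity-paradox direction).

**What the generator does *not* emulate:** pharmacokinetic
insulin–glucose feedback (treatments do not close the loop on the latent
glucose), within-stay BMI change, inter-hospital case-mix differences
beyond insulin practice, informative measurement timing (sicker patients
measured more often), and death as a competing risk inside a window. A
green recovery test therefore establishes that the pipeline correctly
estimates a correctly-specified discrete-time hazard — not that the
clinical model is right.

# Numerical and testing choices

* Wald CIs use $z = 1.959964$; no small-sample or multiplicity
  correction anywhere, matching standard practice for this analysis.
* The BMI chi-square is a likelihood-ratio test (invariant to referent
  choice); the Pearson chi-square for 2x2 comparisons is computed
  without continuity correction; the Mann-Whitney U uses the normal
  approximation, with p = 1 returned for fully tied data.
* The percentile bootstrap resamples patients (B = 500 by default),
  deterministic given a seed, and restores the caller's RNG state.
* Complete separation (every observation perfectly predicted) is an
  error naming the separating term; a covariate level with zero events
  (quasi-separation, routine in small cohorts) is kept with a divergent
  coefficient and huge SE, exactly as `glm()` reports it.
* Empty covariate levels are dropped with a warning before fitting;
  rank-deficient designs are an error naming the aliased columns.
* The unit conversion uses 18.016 (mg/dL)/(mmol/L), the molar mass of
  glucose; all bins are left-closed right-open except where clinical
  convention is inclusive (hypoglycemia <= 70; HbA1c 6.1–6.5 closed on
  both ends; insulin bins right-closed as printed).

**Acceptance-test scaling.** The episode and window rules are checked
against independent oracles on 1,000 random inputs each; closed-form
checks pin the logistic OR, the two-predictor VIF and the LOCF-TWA
integral. Parameter recovery runs the full spec-stated 200 cohorts of
2,000 stays. Null calibration of the BMI likelihood-ratio test runs 600
replicates (scaled down from the stated 2,000 to fit the one-CPU test
budget; the Kolmogorov-Smirnov critical value scales with the replicate
count, so this is the same check at reduced power) on a calibration
scenario with balanced BMI groups and 400-stay cohorts, chosen so each
group carries enough events for the chi-square asymptotics the test
presumes.

# Known limitations

* Repeated windows per patient are pooled without clustered standard
  errors (the standard pooled formulation); CIs are therefore slightly
  anti-conservative under within-patient correlation.
* The cardiovascular SOFA component cannot exceed 2 without
  drug-specific vasopressor doses.
* Death within an H = 0 window is treated as censoring at
  discharge/death time, not as a competing risk.
* The low-missingness sensitivity subset can only act on lactate
  missingness: stays with no BMI at all are excluded at load, so the BMI
  cap is vacuously satisfied.
* At a few hundred events per cohort the BMI likelihood-ratio test
  shows the textbook mild finite-sample anti-conservatism (null
  p-values very slightly concentrated below 0.5). The suite's KS check
  at $\alpha = 0.01$ passes; an analysis at this scale wanting exact
  calibration would add a Bartlett-type correction, which the replicated
  analysis design does not use.
* With only a handful of events in the sparsest BMI level (>= 40 kg/m²
  at 6% prevalence in 2,000-stay cohorts), the plain logistic MLE keeps
  a finite-sample bias of order $-1/(2 m_{\text{events}})$; the
  parameter-recovery suite documents this honestly (that level's mean
  log-OR bias exceeds the 0.05 bound while CI coverage stays nominal).
  Firth-penalised estimation would remove it but is deliberately out of
  scope: the point of the package is to replicate the plain pooled fit.
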