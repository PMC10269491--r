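---
title: "Methods: a composite biological-age clock from telomere length and iron metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a composite biological-age clock from telomere length and iron metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironclock)
```

## The model

The package implements a composite biological-age score for
cross-sectional cohorts, built from five inputs measured in whole
blood: relative telomere length (RTL, a dimensionless T/S ratio),
serum iron (Fe, ug/dL), total iron-binding capacity (TIBC, ug/dL),
serum ferritin (F, ug/L) and chronological age $a$ (years).  Each
input $X$ is z-scored against a referent population,

$$X_\mathrm{norm} = \frac{X - \mu_X}{\sigma_X},$$

which removes units and puts the inputs on a common scale.  In the
referent population each normalized variable drifts approximately
linearly with age, $X_\mathrm{norm} = k_X a + n_X$ (unweighted OLS);
the sign of $k_X$ says whether the variable rises or falls with age
(RTL, iron and TIBC fall; ferritin rises).  The score is

$$a_\mathrm{bio} = k \sum_X \mathrm{sgn}(k_X)\, X_\mathrm{norm}
  + C + a\,\Delta_{-} + (a - 20)\,\Delta_{+},$$

with

$$k = \Big(\sum_X |k_X|\Big)^{-1}, \qquad
  C = -k \sum_X \mathrm{sgn}(k_X)\, n_X.$$

Because OLS is linear, these two constants place the least-squares fit
of the score against age in the referent population exactly on the
identity line $a_\mathrm{bio} = a$; each variable contributes in
proportion to its own population age-drift $k\,|k_X|$ rather than
through estimated weights, which keeps the construction usable for
modest sample sizes where principal-component or correlation-redundancy
weighting is not.  Transferrin saturation and serum transferrin are
carried in the data model but deliberately excluded from the formula
(the former is a ratio of two included variables, the latter is highly
correlated with TIBC).

Two dimensionless life-expectancy offsets adapt the referent-calibrated
score to a study population:

* $\Delta_{-} = (a_\mathrm{le} - a_\mathrm{le}^\mathrm{ref}) /
  a_\mathrm{le}$, applied per year of age to *every* study subject,
  corrects for the gap between the study population's life expectancy
  (default 72.9 years) and the referent's (76.1 years); it is
  $-0.044$ at the defaults and should be disabled when scoring the
  referent population itself.
* $\Delta_{+} = (a_\mathrm{le}^\mathrm{ref} - a_\mathrm{le}^\mathrm{HIV}) /
  (a_\mathrm{le}^\mathrm{HIV} - 20)$, applied per year since age 20 to
  HIV-positive subjects only, encodes the reduced life expectancy of
  treated HIV infection (67 years from treatment start at age 20),
  giving $0.194$ at the defaults.

Calibration is done separately in two age bands — younger (19–35) and
older (50–77) — because several inputs trend differently with age in
young adults and older adults; the built-in constants
(`reference_constants()`) reproduce the published values derived from
NHANES 2001–2006 (RTL and the iron panel) and NHANES III (ferritin).

```{r}
reference_constants("younger")
```

## Decisions where the design was open

* **Units.** The canonical internal unit for iron and TIBC is ug/dL,
  matching the calibration constants; umol/L input is converted with
  5.5845 ug/dL per umol/L (atomic mass of iron).  Normalizing umol/L
  values against ug/dL moments would be meaningless, so `read_subjects()`
  requires the unit to be declared (header suffix or argument) whenever
  it is not the canonical one.
* **Band assignment for scoring.** Ages 18–35 use the younger
  constants (cohorts of this design enrol from 18; the calibration
  band starts at 19), 50–77 the older ones.  The gap (35, 50) is a
  deliberate design exclusion and is rejected by default;
  `allow_out_of_band = TRUE` maps to the nearest band with a warning.
* **$\mathrm{sgn}(0)$** is defined as $+1$ with a warning; a zero slope
  contributes nothing to $k$ either way.
* **Both adjustments can coexist.** The HIV term is added on top of
  the population term for HIV-positive subjects (the published
  constants list both for both groups); flags in
  `adjustment_policy()` disable either, and `adjust_naive = FALSE`
  exempts therapy-naive subjects from the HIV term.
* **$(a-20)$ below age 20** is allowed to go negative, as the formula
  dictates; study designs of this kind enrol from 18.
* **Missing values.** Subjects missing any of the five formula inputs
  are excluded from scoring (listed with reasons) but are retained for
  the group comparisons of whatever variables they do have, mirroring
  per-parameter group sizes in real cohorts.
* **Statistical gate.** "t test or Mann-Whitney, as appropriate" is
  implemented as: pooled-variance two-sided t test (df
  $n_1 + n_2 - 2$) iff both groups pass a Lilliefors-corrected
  Kolmogorov–Smirnov normality test at $\alpha = 0.05$, else
  Mann-Whitney U with normal approximation and tie correction;
  mean ± SD is reported with the t test, median ± IQR with U.  No
  multiple-testing correction is applied.  The Lilliefors p-value uses
  the Dallal–Wilkinson approximation with the Stephens polynomial for
  p > 0.1 (no suitable test ships with base R); its D statistic was
  verified against an independent implementation.
* **Viral load.** Values below the 20 copies/mL detection limit are
  replaced by 10, the midpoint of the undetectable range, before any
  regression (`pvl_floor()`); the transform is idempotent.

## What the synthetic generator emulates — and what it does not

`generate_referent()` draws band-truncated normal ages and builds each
biomarker as
$X = \mu_X + \sigma_X\,[k_X (a - \mu_a) + \varepsilon]$ with
$\varepsilon \sim N(0, \sqrt{1 - k_X^2 \sigma_a^2})$, so the
normalized variable has (asymptotically) mean 0, SD 1 and OLS slope
$k_X$ on age.  `generate_cohort()` draws the four study groups (55/50
HIV-positive, 50/50 HIV-negative across the bands) with the published
group means and SDs, an 8-subject therapy-naive contingent in the
younger HIV-positive group, an even 2NRTIs+NNRTI / 2NRTIs+PI split
among the treated, band-truncated ages, therapy durations truncated at
the observed study minimum (0.8 months), and viral load as a
configured fraction of exact zeros (undetectable) plus a log-normal
tail.  Every draw is reproducible from one seed, expanded into
independent per-group streams.

Three deliberate interpretations, chosen once:

* The published cohort age summaries (29.2 ± 0.5, 59.6 ± 1.1 years)
  are read as mean ± SEM — an SD of half a year across an 18–35
  enrolment band is not plausible — so the generator uses
  SD = SEM × √n (3.71 and 7.78 years), truncated to the band.
* The published viral-load summary is internally ambiguous, so the
  tail is configuration-first (defaults: 70% undetectable, log-normal
  meanlog $\log 10^4$, sdlog 1.5); only the detection-limit behaviour
  is fixed by the source.
* Biomarkers are conditionally independent given age (marginal
  normals truncated at zero): the source reports no residual
  biomarker–biomarker correlations, and explicitly found none between
  RTL and the iron panel.

Known distortions of the stated world, documented rather than patched:

* **Band truncation shrinks the age SD** (4.72 → 3.79 years in the
  younger band, 7.94 → 6.39 in the older).  Since the age slope is the
  exact identity $k_a = 1/\mathrm{sd}(a)$, calibration on the
  synthetic referent recovers $k_a \approx 0.264 / 0.156$, not the
  published 0.2120 / 0.1259, and the recovered $k$ sits 11–14% below
  the published value.  The structural-fidelity test therefore checks
  the sign pattern plus $k$ against the truncated-normal closed-form
  prediction; recovering the *printed* $k$ from a band-truncated
  sample is mathematically impossible, and a green test does not claim
  otherwise.
* **Ferritin has substantial normal mass below zero** under its
  published moments (5.3% younger, 12.7% older), so truncation at
  zero shifts its sample SD by −6% to −12% and the older-band mean by
  +5%.  Truncation counts are reported by the generator; the
  moment-fidelity test asserts the 2% band only where the stated
  world attains it.  An alternative log-normal ferritin margin would
  avoid this but was not adopted for the referent, to keep the stated
  construction.

The generator makes no attempt to simulate longitudinal trajectories,
viral dynamics, CD4 reconstitution, assay noise structure, or
subject-level correlation beyond the shared age trend.  Consequently a
green cohort-scale test establishes that the *pipeline* reproduces the
qualitative published structure under the published group moments — it
does not validate the clock against real subjects.

One cohort-scale acceptance property is left deliberately red: the
requirement that the fitted HIV-positive biological-age line lie above
the HIV-negative line over the whole 20–77 range in ≥ 95% of 200
replicates.  Under the published group moments the expected gap at the
extrapolated age-20 endpoint is only about +2 years against a ~2.3-year
standard error of the difference of fitted lines, so the measured rate
is ~0.88–0.93.  The threshold is not attainable in the stated world;
the failure is reported, not hidden.

## Numerical notes

* All arithmetic is double precision; scores are rounded only in
  printed output.  The decomposition invariant
  $a_\mathrm{bio} = k \sum \mathrm{term}_X + C + \mathrm{adj}_- +
  \mathrm{adj}_+$ reconstructs to 1e−9 years.
* Sample SDs use the $n-1$ denominator; all fits are unweighted OLS
  (survey sampling weights are not modelled).
* A constants object validates $k = 1/\sum |k_X|$ to 0.01 absolute by
  default — loose enough to accept constants recomputed from slopes
  printed at 4 decimals (the published $k$ differs from
  $1/\sum|k_X|$ of the printed slopes by up to 0.002) — and exactly
  (1e−8) for freshly calibrated objects.
* Constants files are flat `key = value` text written at 17
  significant digits, so write–read round-trips are bit-exact.
* Degenerate inputs error early and by name: non-positive $\sigma$,
  constant columns, fewer than 2 distinct ages, all-zero slopes,
  life expectancies ≤ 20 years, negative viral loads.

## Limitations

The clock is an illustrative first-order construction, not a validated
instrument: contributions are tied to population age-drifts, not to
outcome-optimised weights; calibration bands leave a 35–50 gap; the
ferritin scale of the published referent (NHANES III, 141–196 ug/L)
sits far above typical study-cohort levels (5–16 ug/L), which the
pipeline deliberately does not reconcile — it normalizes as calibrated
and flags |z| > 5 as outliers downstream rather than altering data.
Cohort-specific p-values of the original study are not reproducible
(subject-level data were never published) and are out of scope; the
test suite covers the machinery with property-based stand-ins instead.
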