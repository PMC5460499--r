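---
title: "Estimating excess mortality after hip fracture from claims data"
author: "fracexcess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating excess mortality after hip fracture from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fracexcess)
```

## The estimation problem

Hip fracture in older adults is followed by a burst of mortality in the
first months and a persistent elevation for years. Estimating that excess
from an administrative claims database requires reconstructing a cohort
study from billing records: identifying *incident* fractures, sampling
comparable fracture-free subjects, measuring pre-fracture health from
diagnosis codes, and turning person-time and deaths into risk contrasts
with honest uncertainty. `fracexcess` implements each step behind an
explicit, tested interface; this vignette records the modelling choices
and their rationale.

## Cohort construction

**Cases.** A case is a person's first inpatient claim whose *primary*
diagnosis is S72.0 (femoral neck), S72.1 (pertrochanteric) or S72.2
(subtrochanteric), dated inside the enrolment window (default
2005-01-01 to 2013-12-31), at age ≥ 50, with no earlier hip-fracture
claim of any kind in the observable history. Restricting to primary
inpatient diagnoses avoids counting follow-up visits and transfer codes
as new fractures; requiring a clean history makes the case incident
rather than prevalent. The index date is the claim's first day of care.

**References.** Each case is matched to up to 4 persons of the same sex
and birth year who, on the case's index date, are alive, inside their
coverage window, and free of any hip-fracture claim. Sampling is without
replacement *globally*: a person serves as a reference at most once, so
the total reference count is exactly `ratio × n_cases` minus the
shortfall from exhausted strata. Two deliberate subtleties:

- A reference who fractures *after* the index date stays in the
  reference arm for that matched set, and that later fracture can still
  found the person's own case record. Excluding future cases from the
  reference pool would condition on the future — early deaths cannot
  fracture later, so a "never became a case" pool is enriched with early
  deaths and overstates reference mortality. (This effect is measurable
  in simulation: with strongly elevated incidence it biases the excess
  risk downward by about two percentage points.)
- Candidate order is randomized by the run seed; ties are never broken
  by identifier order, so no systematic selection can leak through ID
  assignment.

**Follow-up** runs from the index date to death or the closure date
(default 2016-05-04). All month arithmetic uses a fixed month of
365.25/12 days so person-time conservation is exact; a subject dying on
the index date receives half a day of exposure rather than zero.

## Comorbidity

The Charlson index is computed from ICD-10 claims with the Quan coding
algorithm (17 condition categories as prefix lists, shipped as an
editable CSV) and the 2011-updated weights by default; the original 1987
weights are packaged for comparability work. A category is accepted for
a given index date if it appears

a. among secondary diagnoses of the index-date inpatient claim, or
b. on at least one inpatient claim in the half-open 365-day lookback
   `[index − 365, index)`, or
c. on two or more *outpatient* claims in that window at least 7 days
   apart.

Rule (c) is the standard guard against rule-out and billing-artefact
codes. Two readings of "at least 7 days apart" are possible; the package
uses the weaker any-pair reading (maximum pairwise gap ≥ 7 days), which
is documented here precisely so it is testable. Hierarchy pairs
(mild vs moderate/severe liver disease, diabetes without vs with
complications, any malignancy vs metastatic solid tumour) score only the
severer member. The score enters models as an integer linear covariate,
truncated at 10 for stability.

## Mortality model and risk curves

Follow-up is split on a graduated grid — cut points every 0.5 months to
3, every month to 12, every 3 to 24, every 6 to 48, every 12 to 120
(29 cut points) — dense where post-fracture mortality changes fastest.
Within an interval the hazard is constant (piecewise-exponential model),
so Poisson regression on interval deaths with log person-time offset
estimates interval rates.

The crude model (arm × interval) is saturated; its fitted rates equal
deaths/person-time cell-wise, so the package computes them in closed form
and keeps the iterative GLM only as a test oracle. The adjusted model
adds CCI and centred age with fracture×interval, fracture×CCI,
fracture×age and interval×age interactions, fitted by `stats::glm` after
aggregating subject-intervals over identical covariate patterns (the
Poisson likelihood is additive, so aggregation changes nothing);
convergence uses a 1e-10 epsilon with up to 100 iterations.

Rates chain into cumulative risk via
`p_i = 1 − exp(−λ_i Δ_i)`, `CR(t_k) = 1 − Π_{i≤k}(1 − p_i)`. Cells with
zero person-time carry an undefined rate and are skipped with a warning;
cells with zero deaths are kept (a zero rate is information).

**Standardization.** Adjusted risks for both arms are predicted at every
covariate pattern of the *case* arm, chained per pattern, and the risk
curves averaged across patterns (model-based standardization). Averaging
per-pattern curves — rather than averaging interval probabilities and
chaining the average — is deliberate: population survival is the mean of
pattern survivals, and chaining averaged probabilities inflates late
risk under wide covariate heterogeneity (by several points over a
50–100 age span). Standardizing both arms to the case distribution makes
the excess an exposed-standardized contrast, matching the attributable
framing of the effect measures. Stratum curves (e.g. by sex) aggregate
as point-wise means weighted by case-group stratum sizes.

## Effect measures and the bootstrap

At a horizon t, with CR₁ the case and CR₀ the reference cumulative risk:
excess risk ER = CR₁ − CR₀, risk ratio RR = CR₁/CR₀, attributable
fraction AF = ER/CR₁ = 1 − 1/RR. Confidence intervals come from
resampling *matched sets* with replacement — resampling individuals
would break the matched design. Risks and differences get bias-corrected
(BC) percentile intervals: with `z0 = Φ⁻¹(F_boot(θ̂))` the endpoints are
the bootstrap quantiles at `Φ(2z0 ± z_{α/2})`. Ratios get plain
percentile intervals, as does the AF (a monotone transform of RR). BC
rather than BCa: the acceleration constant needs jackknifing over
thousands of sets for little gain, and median-bias correction alone is
deterministic and transparent. Replicates recompute the crude pipeline
in closed form (the adjusted model is refitted when requested); matching
is *not* redone — inference is conditional on the observed matched sets.
Ratios whose bootstrap coefficient of variation exceeds 0.5 are flagged
unreliable via an attribute.

## The synthetic generator

Because the source claims database cannot be redistributed, the package
generates claims-shaped populations with known hazards:

- **Demographics**: configurable size, 41% male, starting ages drawn
  from decade weights (0.35, 0.27, 0.22, 0.12, 0.04 for 50s…90s).
- **Baseline mortality**: Gompertz per sex, λ₀(a) = b·exp(θa) per
  person-year (defaults b = 2.4e-5, θ = 0.095 for men; b = 8.5e-6,
  θ = 0.105 for women).
- **Comorbidity**: independent category draws at fixed prevalences
  (reference-arm mean score ≈ 0.7); each planted point multiplies the
  death hazard by `cci_hr` (default 1.35) and the fracture hazard by
  `frac_cci_hr` (default 1.3 — switchable confounding).
- **Fracture incidence**: piecewise-constant per sex and age decade,
  rising steeply with age.
- **Fracture effect**: the death hazard is multiplied from the fracture
  date by `h(u) = 1 + A·exp(−u/τ) + B` (u in months; defaults A = 13,
  τ = 2.5, B = 0.5) — a large early excess decaying to a persistent
  plateau, the two phenomena the method must detect.
- **Claims emission**: true categories produce yearly evidence — one
  inpatient claim or an outpatient pair ≥ 7 days apart; decoy categories
  appear exactly once, or twice under 7 days apart, and must be rejected
  by a correct scorer; non-Charlson background claims add noise.

The preset's rates were chosen once so the analytic cumulative-risk
magnitudes sit in the range published for an Eastern European 50+
cohort (crude 1-year case mortality 20–35%); it is a convenience preset,
not a calibration claim. Event times are drawn exactly: Gompertz times
by closed-form inversion, fracture times by piecewise-exponential
inversion across age bands, post-fracture death times by 60-step
bisection on the closed-form cumulative hazard (precision far below a
day). Everything is deterministic given one integer seed.

**Ground truth.** `true_cumulative_risk()` evaluates
`1 − exp(−∫λ)` in closed form. The reference arm needs care: its members
may fracture after the index date, so the reference truth is a two-state
quantity — fracture-free survival plus the integral over fracture times
of (reach fracture-free) × (fracture rate) × (post-fracture survival) —
evaluated by Simpson quadrature on 401 nodes (the integrand has kinks at
age-band boundaries, which caps Simpson's order; 401 nodes keep the
error near 1e-5). Tests check both truths against fine-grid Riemann
oracles.

## What the simulations do and do not show

The generator emulates the *structure* the estimator relies on —
age/sex-graded baseline mortality, claims-coded comorbidity with
imperfect ascertainment patterns, incident fractures with an
early-peaked persistent effect — and therefore supports parameter
recovery: on a 50,000-person cohort with eightfold incidence (≈10,000
cases, used so the Monte Carlo error of the check is small against the
tolerance) the crude 5-year excess risk lands within 1.5 points of the
analytic truth; planted constant rate ratios are recovered within 3
standard errors; under a null effect all fracture terms are within 3 SE
of zero; and 95% BC intervals cover the truth 91–99% of the time over
200 repetitions (n = 5,000, 400 bootstrap replicates). The test suite
runs these at exactly those sizes.

It does not emulate real claims pathologies: coding drift over calendar
time, provider-level coding styles, correlated comorbidity onset,
emigration loss to follow-up, or duplicate/contradictory records beyond
simple decoys. Passing tests certify the estimator against the stated
generating process, not against every artefact of a production claims
feed.

## Numerical and degenerate-input conventions

- ICD-10 codes are stored dotted and upper-case; matching is prefix
  based. Undotted inputs are normalized (`"S720"` → `"S72.0"`).
- Dates are ISO-8601 calendar dates; all date arithmetic is whole days;
  months are 365.25/12 days everywhere.
- Death on the index date → 0.5 days of person-time, event counted.
- Deaths beyond the 120-month grid end are censored at the grid end.
- Zero-person-time cells are dropped from risk chaining with a warning;
  an all-zero-rate curve is identically zero.
- Bootstrap replicates that fail (e.g. an empty resample cell) are
  redrawn up to three times; more than 5% failures abort the run.
- The matcher warns (attribute `short_sets`) when a stratum cannot
  supply the full ratio; a set of 1 case + 0 references is kept, not
  fatal.

## Known limitations

- The adjusted model treats age as fixed at index; covariates are not
  updated during follow-up.
- "Age adjustment within age groups" in the source analysis is realized
  here as marginal standardization to the case arm; the original
  procedure is not recoverable from its description, so this is the
  package's principal interpretive decision.
- No competing-risk decomposition (all-cause death only), no
  cause-of-death analysis, no alternative comorbidity scores, and no
  spline/smooth-hazard models — the piecewise grid is the model.
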