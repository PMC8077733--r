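---
title: "Learning extreme heat exposure definitions with heatlogic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning extreme heat exposure definitions with heatlogic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health effects of extreme heat are usually estimated with a binary
exposure — "a heat wave day" — but the definition of that exposure varies
wildly across studies: which daily heat metric, which percentile
threshold, and which lag/duration pattern. `heatlogic` inverts the usual
workflow: instead of pre-specifying the definition, it estimates the
Boolean rule H(**X**) over lagged exceedance indicators that best explains
the outcome series, within a time-series regression framework that
controls seasonality, long-term trends, calendar effects and the
continuous (non-extreme) part of the temperature response.

This vignette documents the model, the search procedure, the synthetic
data generator, the numerical choices, and what the package's validation
does and does not demonstrate.

## From hourly weather to binary indicators

Hourly dry-bulb and dew-point temperature are summarised to six daily
metrics: the maximum, minimum and average of dry-bulb temperature (TMX,
TMN, TAvg) and of apparent temperature (ATMX, ATMN, ATAvg), where
apparent temperature combines heat and humidity as
AT = −1.3 + 0.92·T + 2.2·e with e the water vapor pressure in kPa. The
package derives e from the dew point with the Magnus–Tetens saturation
formula over water (constants 6.112 hPa, 17.62, 243.12 °C); the
conversion is isolated in `water_vapor_pressure()` so an alternative
formula can be swapped in.

Days with fewer than 18 of 24 hourly observations are set missing — a
completeness rule that rarely binds for airport-quality records.
Percentile thresholds (95/98/99) use linear interpolation between order
statistics (quantile type 7), so thresholds are bit-reproducible, and a
day is *extreme* only when its metric **strictly exceeds** the threshold
(ties are non-extreme). By default the threshold basis is **every day of
the record**, not only warm-season days: with an all-year basis, the top
2% of days all fall in summer, which yields warm-season exceedance
frequencies near 2% of the *whole* record (about 146 days per 20 years at
the 98th percentile) and is what makes rare but clustered multi-day
events available to the tree search. A warm-season-only basis is
available through the `basis_dates` argument of
`percentile_threshold()`.

Lagged indicators X₁ = lag-0 exceedance, X₂ = lag-1, … are built from the
full calendar record, so early-May model rows use late-April weather
rather than being dropped; model rows themselves are always restricted to
May 1 – September 30.

## The time-series model

Daily counts are modelled as overdispersed Poisson with log link:

ln μ_t = β₀ + β·H(**X**_t) + ns(T_t) + ns(T̄_t) + ns(DPT_t) + α₀,year +
f(DATE_t)×α₁,year + Σλᵢ·DOWᵢ + Σδⱼ·HOLIDAYⱼ + Σγₖ·HOSPITALₖ

* `ns(·)` are natural cubic splines with 2 internal knots placed at the
  interior thirds of the observed range (boundary knots at the observed
  min/max). Because T_t and the lag-1–3 mean T̄_t are truncated at the
  extreme threshold in the primary analysis, the splines describe only
  the sub-threshold response and H carries the entire above-threshold
  contrast. The non-truncated option is available and changes the
  interpretation of β to the *added* effect of extreme days beyond the
  continuous response. T̄_t averages the truncated series in the
  truncated analysis, keeping the two covariates on the same scale.
* The seasonal smooth f uses monthly knots (Jun 1, Jul 1, Aug 1, Sep 1 on
  the day-of-season axis, boundary at May 1 / Sep 30) and is interacted
  with year, giving each year its own within-season shape; year
  indicators (first year as reference) absorb between-year level shifts.
* Day-of-week uses Sunday as reference; holiday and hospital-availability
  indicator columns are taken from the input data as supplied, with
  constant columns dropped (a column that never varies is
  unidentifiable). The dew-point spline is omitted when apparent
  temperature is the exposure of interest, since AT already encodes
  humidity.

The fit is standard IRLS (via `stats::glm.fit`, convergence 1e-8, max
100 iterations); the dispersion φ̂ is the Pearson χ²/(n−p) estimator and
the coefficient covariance is φ̂·(XᵀWX)⁻¹. Model comparison across grid
cells uses QAIC = deviance/φ̂ + 2p with each candidate's own φ̂; because
all cells share the same covariate backbone, φ̂ is stable across cells,
and a shared-φ variant is available through the `phi` argument of
`qaic()`.

## The three-stage algorithm

Stage 1 fits the model without H. Stage 2 regresses the Pearson residuals
r_t = (Y_t − μ̂_t)/√(φ̂·μ̂_t) on candidate logic trees; stage 3 refits the
full model with the selected H and reports RR = exp(β̂) with a 95% Wald
interval. The multi-stage design keeps the confounder model fixed and a
priori while the data-driven search only explains residual variation.

### The tree search

A logic tree is a full binary tree: internal nodes are AND/OR, leaves are
indicators or their complements (NOT is confined to leaves; complementing
a whole tree propagates by De Morgan's laws). Scoring is least squares of
the residuals on the tree's 0/1 output — the natural continuous-response
score, for which the minimizing intercept/slope are the group means. Since
the score depends on a tree only through its values on the at most 2^k
observed indicator patterns, rows are collapsed once to per-pattern
sufficient statistics and each candidate tree costs O(2^k) to score,
which makes annealing over thousands of iterations cheap even for
20-year series.

Simulated annealing explores the classical seven-move neighborhood
(alternate leaf, complement leaf, alternate operator, grow branch, prune
branch, split leaf, delete leaf) with Metropolis acceptance
min{1, exp(−Δ/temperature)} and geometric cooling. Fixed control
parameters rarely transfer between problems, so the package
auto-calibrates them:
a short random walk estimates the typical uphill score change, the start
temperature is set so such moves are accepted with probability ≈ 0.9 and
the end temperature so terminal acceptance is ≈ 10⁻³; defaults are 25 000
iterations and 5 restarts (`annealing_schedule()`, `anneal_logic_tree()`),
with shorter schedules used inside cross-validation. All randomness is
seed-controlled; ties in the objective are broken toward the simplest
canonical DNF (fewest literals, then lexicographic clause order) so
results are reproducible and parsimonious among score-equivalent trees.

Tree size (number of leaves) is selected by ten-fold cross-validation
with random day-level folds: each size is annealed on the training folds
and evaluated by held-out residual sum of squares; the smallest size wins
ties. The default candidate sizes are 1–3, matching a search over
positive tree sizes; offering size 0 (the no-exposure model) is supported
and turns stage 2 into a test of whether any exposure is warranted — the
pipeline then reports the stage-1 model for that cell as a null finding.
Day-level random folds (rather than contiguous blocks) match the
cross-validation of the classical logic-regression implementation;
block-structured folds can be emulated by pre-filtering rows.

Because least squares cannot distinguish a rule from its complement (the
two fits swap group means), every final tree is oriented so that exposed
days are the minority — the reference group H = 0 is the more frequent
day type — which resolves the ambiguity exactly as a frequency-based
reporting rule should.

### Equivalence and rendering

Different trees can classify identically; the canonical reporting form is
the disjunctive normal form obtained by the distributive law with
contradiction removal, deduplication, absorption, and canonical sorting,
rendered as e.g. `(lag0 AND lag1) OR (lag1 AND lag3)`. Exhaustive
truth-table comparison (`trees_equivalent()`, feasible for the small k
used here) backs the test suite, and `exhaustive_best_tree()` enumerates
all representable Boolean functions on small instances as an independent
optimum reference for the annealer.

## The synthetic data generator

The generator emulates the structure of a long airport weather record and
of warm-season ED counts; it is the package's study condition, not a
tuning knob.

* **Weather.** Daily mean temperature = annual sinusoid (peak mid-July,
  amplitude 9.5 °C around 17 °C) + AR(1) anomaly (ρ = 0.75, innovation SD
  1.6 °C); hours add a diurnal sinusoid (amplitude 5 °C, minimum ~3 am)
  and N(0, 0.3²) noise; dew point tracks the dry bulb minus a slowly
  varying positive offset (mean 4 °C). ρ and the innovation SD were
  calibrated once so that 20 seasons carry ≈146 lag-0 ATMN-98 exceedance
  days, ≈73 two-day-run days and ≈29 ended-two-day-run days — the
  E1/E2/E3 frequencies that drive statistical power for the three planted
  scenarios (measured values across seeds: ≈147/69/30).
* **Counts.** Negative binomial with the quasi-Poisson variance function
  (variance = φ·mean, i.e. size = μ/(φ−1); φ = 1 falls back to Poisson),
  log-mean = seasonal sinusoid + day-of-week + linear year trend +
  holiday dips, intercept calibrated so the average mean matches the
  profile (CIRC ≈ 623/day, RENAL ≈ 139/day, HEAT ≈ 2.5/day). The
  overdispersions (CIRC 2.0, RENAL 1.5, HEAT 1.2) are fixed package
  choices in the plausible range for adjusted daily ED series of those
  magnitudes. The exposure multiplies the mean by RR on days where the
  scenario rule fires: E1 H = X₁, E2 H = X₁∧X₂, E3 H = X₁ᶜ∧X₂∧X₃ (lags
  0–2 of ATMN-98).

What the generator does **not** emulate: real exceedance runs are driven
by synoptic weather patterns rather than a single AR(1); humidity and
temperature extremes co-occur more strongly than the independent offset
process implies; real counts have data-quality artifacts (hospital
dropout, coding changes) beyond smooth trends. Passing the simulation
study therefore demonstrates that the estimation machinery recovers
planted truth under realistic frequencies and noise — not that any
particular real-data finding is correct.

## The simulation study

`run_simulation_study()` evaluates, per scenario × true RR × outcome
profile: relative bias mean(RR̂ − RR)/RR and RRMSE √(mean((RR̂ − RR)²))/RR
of the logic-regression arm and of a known-exposure comparator (stage 2
skipped, truth tree injected), plus average day-level sensitivity and
specificity of the recovered exposure classification against the planted
rule (computed per replicate, then averaged). One weather realization is
shared across replicates by default — mirroring a design built on
observed meteorology — with per-replicate redrawing available. The
simulation fixes the grid to the truth metric (ATMN at the 98th
percentile) and offers lags 0–2 to the search, matching the scenario
definitions; full-grid recovery is a separate, heavier experiment
exercised in the test suite at reduced scale. Replicates in which no tree
is selected enter sensitivity/specificity as an all-unexposed
classification and are excluded (and counted) from the RR summaries.

Expected qualitative behaviour, asserted in the tests: performance
improves with higher RR and higher counts; sensitivity decreases from E1
to E3 as the exposure gets rarer; when trees are imperfectly recovered
the logic-regression RR is attenuated toward the null (negative relative
bias) relative to the known-exposure arm — classical exposure
misclassification.

### Problem sizes used in the shipped experiments

The packaged validation runs 20 synthetic warm seasons (3060 analysis
days), 20 replicates per cell, cross-validation annealing of 1000
iterations and final annealing of 4000 iterations × 2 restarts. These
sizes were chosen so that the full suite completes comfortably on a
single CPU while leaving Monte-Carlo error well inside the tolerances the
checks assert; the defaults for interactive use are larger (25 000
iterations, 5 restarts, 100 replicates).

## Numerical choices and degenerate inputs

* Quantile type 7, strict exceedance, ≥18-hour daily completeness, IRLS
  tolerance 1e-8: all stated above and configurable where scientifically
  meaningful.
* Constant tree output scores the total sum of squares with zero slope;
  an all-zero indicator matrix short-circuits stage 2 to a null result.
* A design that loses full rank (e.g. collinear indicator columns) stops
  with the offending block named; constant holiday/hospital columns are
  dropped with a message instead.
* Exactly 50/50 exposed/unexposed splits are left unoriented with a
  warning.
* Seeds: every exported stochastic function takes a `seed`; internal
  child seeds are derived with a fixed integer hash and stay below 2³¹.

## Known limitations

* Single-tree models only; multiple-tree and Bayesian/penalized logic
  regression are out of scope.
* The Wald CI of the stage-3 RR ignores the uncertainty of the estimated
  exposure definition; for rare exposures this understates total
  uncertainty. The simulation study quantifies the resulting attenuation
  but the package does not propagate it.
* QAIC comparisons across grid cells use each cell's own dispersion; with
  very small counts (HEAT-like outcomes) φ̂ itself is noisy and selection
  is less stable — visible in the simulation study as lower sensitivity
  for the low-count profile.
* The generator's AR(1) exceedance clustering approximates, but does not
  replicate, observed meteorology; quantitative agreement with any
  specific real-data analysis is not expected for low-count outcomes.
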