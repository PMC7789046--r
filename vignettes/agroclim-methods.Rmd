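---
title: "Phenology-linked agro-climate indicators for winter wheat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-linked agro-climate indicators for winter wheat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroclim)
```

`agroclim` links daily weather to the biological clock of a winter-wheat crop.
Its chain is: simulate the crop's development stage (DVS) from temperature;
resolve weather-sensitive growth windows from the simulated DVS rather than
from fixed calendar dates; score each window with drought/wetness/cold/heat
indicators; and, on top of that, search for variety thermal requirements that
minimize climate impact and quantify disease risk from indicator-severity
pairs. This vignette describes each model, its assumptions, the tunable
parameters and the numerical choices.

## Thermal-time phenology

### The two-phase model

Crop development is expressed as a development stage DVS that runs from 0 at
sowing through 1 at flowering to 2 at maturity. Each day contributes the
*effective temperature*

$$E_i = \max\big(0, \min(T_i - T_b,\; T_{max,e})\big),$$

with $T_i$ the daily mean temperature, base temperature $T_b$ (0 °C for
winter wheat) and a cap $T_{max,e}$ (30 °C) above which development does not
accelerate further. During the vegetative phase the daily increment is
$E_i V_i P_i / \mathrm{TSUM1}$, where $V_i, P_i \in [0,1]$ are the
vernalization and photoperiod factors; after flowering the increment is
$E_i/\mathrm{TSUM2}$, uncorrected. TSUM1 and TSUM2 are the thermal
requirements (growing degree days, GDD) of the vegetative and reproductive
periods; 600–1000 GDD each is the typical range for Mediterranean durum
varieties.

Conventions that the equations alone do not fix, and how this package fixes
them:

* DVS is 0 on the sowing day; accumulation starts the following day.
* When a day's increment crosses DVS = 1, the residual fraction of that day
  accrues under TSUM2, so no thermal time is discarded.
* The factors multiply the whole capped increment ($E_i V_i P_i$), not the
  raw temperature difference.
* Seasons that do not reach maturity by the end of the series produce a
  track flagged incomplete rather than an error, so parameter scans over
  extreme TSUMs stay total.

### The six-sub-phase model

The multi-phase model splits the season into six sub-phases
(sowing–emergence, emergence–tillering, tillering–stem elongation, stem
elongation–booting, booting–flowering, flowering–ripening), each with its own
TSUM and base temperature; DVS runs 0–6 with integer boundaries between
sub-phases. The vernalization and photoperiod factors apply to sub-phases
2–5 only. Default parameter ranges and base temperatures
(`subphase_parameter_table()`) represent typical Italian durum wheat:

```{r}
subphase_parameter_table()
```

At a boundary crossing the residual day fraction accrues under the next
sub-phase's TSUM and base temperature; DVS advances at most one integer
boundary per day (with realistic TSUMs a double crossing cannot occur, the
clamp only guards degenerate inputs).

### Vernalization and photoperiod

The factor forms are clamped-linear, the convention of WOFOST-family crop
models. Vernalization tracks accumulated "effective vernalization days":
each day contributes 0–1 through a piecewise-linear effectiveness curve
(zero outside −4…17 °C, fully effective at 3–10 °C); the factor rises
linearly from 0 at `v_base` (default 0) to 1 at `v_sat` (default 40
effective days). The photoperiod factor rises linearly from 0 at a critical
daylength (8 h) to 1 at an optimal daylength (16 h), with daylength from
standard solar geometry. **These defaults are package defaults for a
winter-wheat-like response, not calibrated values**; any serious application
should recalibrate them per variety. Passing `vern = NULL` / `photo = NULL`
fixes the corresponding factor at 1, which is also how the package's own
arithmetic checks are run.

### Stage-to-DVS mapping

Indicator windows are worded in terms of growth stages (tillering, booting,
heading, …). The two-phase model only pins emergence (0), flowering (1) and
maturity (2); intermediate stages are mapped through a configurable table
(`stage_dvs_map()`) following WOFOST-convention ordering (tillering 0.15,
stem elongation 0.35, booting 0.75, heading 0.90). "End of flowering" is
flowering + 0.15 DVS by default, because flowering duration is not a model
output. In the multi-phase model the sub-phase boundaries are the stages;
heading, which is not a boundary, is placed at DVS 4.6 inside
booting–flowering. The pre-sowing window is the 30 days before sowing.
All of these are deliberate, exposed defaults, not facts about any
particular variety.

## Water balance and the non-parametric SPEI

Atmospheric water demand is estimated with the precipitation-modified
Hargreaves–Samani equation (Droogers & Allen 2002):

$$ET_0 = 0.0013 \cdot 0.408\, R_a \, (T_{avg} + 17.0) \,
\max(TD - 0.0123 P,\, 0)^{0.76},$$

with $R_a$ the FAO-56 extraterrestrial radiation, $TD = T_{max} - T_{min}$
and $P$ daily precipitation. The 17.0 °C offset is configurable (a 17.8
variant circulates in the literature). A negative radicand and a negative
temperature factor are both clamped so $ET_0 \ge 0$; the sunset-hour-angle
argument is clamped to $[-1, 1]$ so polar night yields $R_a = 0$ exactly.
The daily climatic water balance is $D = P - ET_0$.

The SPEI standardizes the balance aggregated over a window without fitting a
parametric distribution. The window aggregate is ranked among the same
month-day window's aggregates across all years of the record (the evaluated
year left in by default; a leave-one-out switch exists), converted to a
probability by a plotting position, and mapped through the standard-normal
quantile function. The default plotting position is Gringorten,
$p = (r - 0.44)/(n + 0.12)$, the standard choice for non-parametric
standardized drought indices: with it, standardizing every member of its own
reference gives a sample with mean 0 and standard deviation ≈ 0.91–0.96 for
$n \ge 30$, i.e. close to the unit variance the index promises. The Weibull
position $r/(n+1)$ is available as an option but is noticeably
under-dispersed at these sample sizes (sd ≈ 0.86 at $n = 30$). At least 10
reference years are required and fewer than 30 triggers a warning. Because
probabilities stay strictly inside (0, 1), |SPEI| is implicitly bounded
(≈ 2.6 at $n = 30$); no explicit cap is applied.

SPEI values are classified into seven bands: moderate (−1.5, −1], severe
(−2, −1.5], extreme ≤ −2 drought, mirrored for the wet side, `normal` in
between. Band edges belong to the more severe class — the interval wording
is ambiguous at the edges and this choice is conservative.

## The sixteen indicators

`indicator_registry()` encodes the co-designed set: six SPEI windows
(pre-sowing, sowing–emergence, tillering, stem elongation–booting,
heading–maturity, whole season), a pre-sowing rainfall cumulate, wet-day
counts above 10/40 mm (tillering) and 5/40 mm (heading–maturity), the
longest run of days above 5 mm (heading–flowering, flowering–maturity),
days with tmin below 2 °C (booting–flowering) and days with tmax above
28 °C (booting–end of flowering, end of flowering–maturity). Inequalities
are strict ("above 5 mm" excludes exactly 5 mm), matching the indicator
wording; a `strict = FALSE` switch exists. Day counts are returned raw:
impact thresholds are site- and variety-specific and should come from local
impact data, so the package does not pretend to classify them.

Windows resolve either dynamically (from a simulated track) or statically
(from a month-day stage calendar, default an Italian October-sown schedule).
A window the season never reached yields `NA` with a `season_complete`
flag rather than an error.

## Variety optimization

`grid_scan()` enumerates TSUM1/TSUM2 combinations exhaustively with the
two-phase model, the data behind hazard maps. For the six-dimensional
sub-phase space, exhaustive search is impractical and `ga_optimize()` runs a
real-valued genetic algorithm: tournament selection (size 3), uniform
crossover (probability 0.9), per-gene Gaussian mutation (probability 0.1,
SD 10 % of the gene range, clipped to bounds), elitism 1, population 50,
200 generations by default. Elitism makes the best-so-far fitness
non-decreasing; the whole run is deterministic given the seed. Repeated
fitness evaluations of the same chromosome are cached within a run.

The fitness function is this package's own concrete definition of the
stated optimization goal — hydrological indicators inside the safe band,
heat exposure as short as possible: each selected SPEI indicator contributes
a hinge penalty $\max(0, |SPEI| - 1)$; each day-count indicator contributes
its count divided by its window length; penalties are weighted, summed and
negated, so 0 is the best attainable score. A non-maturing season scores a
fixed −10, dominating any feasible penalty so the search is repelled from
non-viable varieties. The absolute scale of these scores is
artifact-defined; only their ordering matters to the optimizer.
`ga_optimize_ensemble()` averages the fitness over ensemble members with
equal weights. A `discretize` argument snaps genes to an even grid, which
is how the GA is compared against exhaustive enumeration in the tests.

## Disease risk from indicator–severity pairs

Observation pairs (indicator value, disease severity) are mapped to
pseudo-observations $u_i = \mathrm{rank}(x_i)/(n+1)$ (average ranks on
ties), which makes the fitted dependence invariant to any strictly monotone
transform of either margin. The copula density is estimated with the
probit-transformation kernel estimator: a Gaussian product-kernel density
with Silverman bandwidths ($\sigma n^{-1/6}$ per margin) fitted on the
normal scores $(\Phi^{-1}(u), \Phi^{-1}(v))$ and back-transformed. This
estimator cannot leak mass outside the unit square and integrates to 1 by
construction (the tests verify the quadrature to within 2 %).

Conditional exceedance $P(\text{severity} > s \mid \text{indicator} = x)$
is computed in closed form: along the conditioning slice the kernel mixture
integrates analytically via the normal tail function, so no quadrature
error enters in the severity direction. `risk_threshold()` scans the
distinct observed indicator values — the indicators here are whole-day
counts, so thresholds in fractional days would be spurious precision — and
returns the smallest value whose exceedance reaches the requested
probability, or an explicit `NA` sentinel (with the maximum probability
attained attached) when the level is never reached. The kernel, bandwidth
rule and any severity pre-transformation are not pinned down by prior art;
all are exposed as configuration with the defaults above.

## The synthetic weather generator

Every component is testable without external data through
`generate_series()`: daily mean temperature is an annual sinusoid (mean
15 °C, half-amplitude 9 °C, coldest mid-January) plus Gaussian noise
(2 °C), a fixed diurnal range (10 °C), and precipitation from a Bernoulli
occurrence process (wet-day probability 0.25, optionally monthly) with
gamma-distributed wet-day amounts (mean 8 mm, shape 0.8 — right-skewed
daily rainfall). These defaults describe a Mediterranean lowland site
suitable for October sowing. Ensembles derive member seeds as
`seed + member index`, so they are reproducible and members are
independent realizations of the same climate.

What the generator deliberately does **not** emulate: temperature–
precipitation correlation, precipitation autocorrelation (wet spells arise
only by chance), heat waves and cold spells with realistic persistence,
inter-annual variability beyond sampling noise, and any spatial structure.
Passing tests therefore demonstrate the correctness of the computational
chain and the stated statistical properties under a plausible climate — not
calibration against any observed site.

## Problem sizes and numerical choices

The test suite simulates seasons of 2–3 synthetic years for phenology
checks (100 random seasons against literal day-loop transcriptions of both
recurrences, tolerance 1e-9), 12–13-year series for SPEI-bearing indicator
checks (so the empirical reference has 11–12 years), a 3-level-per-gene
discretization (729 combinations) for the GA-versus-enumeration comparison
(20 seeded runs, population 40, 60 generations), and 20 seeded replicates
of 60 observation pairs for the switch-point recovery of the disease-risk
chain. These sizes were chosen as the smallest at which each property is
sharply testable.

Degenerate inputs are handled explicitly rather than silently: weather
gaps, inverted tmin/tmax, negative precipitation, unparsable dates and
out-of-range latitudes raise classed validation errors naming the first
offending date; an all-tied margin is rejected by the copula fit; infeasible
GA bounds and out-of-bounds chromosomes are errors; `NaN` SPEI input is an
error rather than a propagated `NaN`.

## Known limitations

* The vernalization/photoperiod parameterizations are uncalibrated
  defaults; dynamic windows in early spring are sensitive to them.
* The static stage calendar is a single Mediterranean schedule; other
  regions need their own anchors.
* The empirical SPEI needs ≥ 10 (ideally ≥ 30) years of weather; it cannot
  be computed from a single season.
* Sub-daily records, missing days and unit auto-detection are deliberately
  rejected rather than repaired.
* The GA optimizes a single scalarized objective; competing objectives
  (yield potential vs. heat avoidance) are expressed only through weights,
  not as a Pareto front.
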