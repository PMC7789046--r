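# agroclim

Phenology-linked agro-climate risk analysis for winter (durum) wheat.

Fixed calendar windows are the wrong coordinate system for crop risk: a heat
wave in late May is harmless to a variety that matured in April and damaging
to one still filling grain. `agroclim` therefore ties every indicator to the
crop's *biological* clock. It is written for agronomists, breeders and
climate-service developers who have daily weather (observed, forecast
ensemble, or projection) and want phenology-aware risk numbers per season.

The package provides, end to end:

* **Thermal-time phenology** — daily development stage (DVS) from the
  two-phase model
  (DVS 0 → 1 → 2: sowing, flowering, maturity;
  `dDVS = max(0, min(T − T_b, T_max,e)) · V · P / TSUM`, with vernalization
  factor `V` and photoperiod factor `P` active in the vegetative phase) and
  a six-sub-phase model (DVS 0 → 6) with per-phase thermal requirements and
  base temperatures.
* **16 agro-climate indicators** over static or DVS-resolved windows:
  hydrological balance via a non-parametric SPEI
  (climatic water balance `D = P − ET0`, modified Hargreaves–Samani `ET0`,
  rank-based standardization `SPEI = Φ⁻¹((r − 0.44)/(n + 0.12))` against
  same-window aggregates across years), wet-day counts, longest wet spells,
  frost (tmin < 2 °C) and heat (tmax > 28 °C) day counts.
* **Variety optimization** — exhaustive TSUM1/TSUM2 grid scans and a seeded
  genetic algorithm over the six sub-phase TSUMs maximizing a
  penalty-based fitness (SPEI inside [−1, 1], minimal heat exposure).
* **Disease risk** — a rank-based kernel copula between an indicator and
  observed disease severity, with closed-form conditional exceedance
  probabilities and whole-day risk thresholds.
* **A seeded synthetic weather generator** (annual temperature cycle +
  Bernoulli/gamma rainfall) so everything runs without external data.

## Worked example

```r
library(agroclim)

# 13 years of synthetic Mediterranean weather, October-sown durum wheat
weather <- generate_series(climate_spec(n_years = 13, seed = 11))
variety <- variety_params_multi(sowing_date = "2011-10-25")
track   <- simulate_multiphase(weather, variety)
track
#> <phenology_track> multiphase, 434 days from 2011-10-25, max DVS 6.000 (complete)
#>   sowing            2011-10-25
#>   emergence         2011-11-11
#>   tillering         2012-02-06
#>   stem_elongation   2012-03-19
#>   booting           2012-04-08
#>   heading           2012-04-15
#>   flowering         2012-04-18
#>   end_of_flowering  2012-04-28
#>   maturity          2012-06-07
```

The sowing-to-maturity cycle is temperature-driven: a warm spring advances
every later stage. Indicators are then scored over the stage windows this
track resolves:

```r
compute_indicators(weather, variety, ids = c(5, 10, 14, 16), spei_warn = FALSE)
#>  id window_start window_end      value risk_class
#>   5   2012-04-15 2012-06-07 -0.3628541     normal
#>  10   2012-04-15 2012-06-07  7.0000000       <NA>
#>  14   2012-04-08 2012-04-18  0.0000000       <NA>
#>  16   2012-04-28 2012-06-07  4.0000000       <NA>
```

Read: the heading–maturity hydrological balance was unremarkable
(SPEI −0.36, `normal`); 7 days above 5 mm of rain fell in that window
(disease pressure); no frost days hit booting–flowering; 4 hot days
(tmax > 28 °C) fell in grain filling. Counts are returned raw — impact
thresholds belong to local calibration.

Searching for the variety that minimizes drought/wetness and heat penalties
in this climate:

```r
cfg  <- ga_config(population_size = 30, n_generations = 40, seed = 7,
                  indicator_ids = c(4, 5, 15, 16))
best <- ga_optimize(weather, variety, config = cfg)
round(best$best_tsum)      # GDD per sub-phase
#> [1] 189  77 112 107  51 539
best$best_fitness
#> [1] -0.0612
```

A fitness of 0 would mean all selected SPEIs inside [−1, 1] and zero hot
days; −0.06 here is the residual heat-exposure fraction the climate does
not allow the crop to escape.

Linking an indicator to disease severity (synthetic pairs with a built-in
jump at 5 wet days):

```r
obs   <- generate_impact_observations(n = 60, switch_point = 5, seed = 1)
model <- fit_copula_density(obs$indicator, obs$severity)
risk_threshold(model, severity_threshold = 40, prob_level = 0.5)
#> [1] 5
```

i.e. from 5 wet days between heading and maturity onward, the conditional
probability of severity above 40 % exceeds one half — the copula chain
recovers the construction.

A thin CLI wrapper ships in `inst/cli/agroclim.R`
(`validate-weather`, `synth`, `waterbalance`, `indicators`,
`disease-risk`).

## Package layout

| Area | Files |
|---|---|
| Weather data model, CSV/ensemble I/O | `R/weather.R` |
| Synthetic weather generator | `R/synthetic.R` |
| Radiation, ET0, water balance | `R/water_balance.R` |
| Non-parametric SPEI | `R/spei.R` |
| Phenology models and windows | `R/phenology.R` |
| Indicator registry and pipeline | `R/indicators.R` |
| Grid scan, fitness, genetic algorithm | `R/optimizer.R` |
| Copula disease risk | `R/disease.R` |

The methods vignette (`vignettes/agroclim-methods.Rmd`) documents the
models, parameter defaults, numerical choices and known limitations.
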