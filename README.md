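# koalasight

Spatial and temporal analysis of citizen-reported wildlife sightings,
built around long-term koala (*Phascolarctos cinereus*) sighting records
from South-East Queensland. Incidental sightings reported by the public
are presence-only data: they cover huge areas for years at negligible
cost, but the reported density confounds animal density with *search
effort* — people see koalas where people go, and people go along roads.
`koalasight` implements the full pipeline for describing such data and
quantifying that bias:

* **cleaning** per the study's inclusion rules (live sightings only;
  same-day same-location repeat reports collapsed; coordinate
  validation) with a reconciled exclusion report;
* **temporal analysis** — monthly series, period aggregates, and the
  classical additive decomposition into trend, seasonal and random
  components;
* **spatial summaries** — tabulations by distance-to-coast band,
  elevation class and polygon attribute;
* **density mapping** — fixed-bandwidth Gaussian kernel surfaces on a
  1 km² grid with Scott's rule bandwidths, classified into
  sighting-density categories;
* **distance covariates** — exact Euclidean distance-transform rasters
  from classified road lines and habitat polygons;
* **point-process inference** — sightings as a spatial point process
  with intensity λ(u):
  * `rhohat()`: nonparametric ρ̂(z) in λ(u) = ρ(Z(u)), the ratio of the
    covariate density at events to the covariate density over the
    window, scaled by n/|W|, with 95% delta-method bands;
  * `berman_test()`: the Berman Z₁ statistic,
    Z₁ = (Σᵢ Z(xᵢ) − nμ)/√(nσ²), standard normal under CSR;
  * `roc_auc()`: point-process ROC/AUC — fraction of sightings captured
    versus fraction of area swept in covariate order (AUC 0.5 = no
    discrimination);
  * `fit_loglinear_ppm()`: the log-linear model λ(u) = exp(α + βZ(u))
    fitted by the Berman–Turner quadrature device (weighted Poisson
    regression over data plus a dummy grid), reporting exp(β) — the
    per-km intensity multiplier — and the percentage change per km.

A first-class synthetic-data generator (`simulation_scenario()`,
`simulate_study()`) emulates the study's record structure, seasonality,
attribute mixes and road-distance effects, so the whole pipeline is
testable offline with known ground truth.

## Worked example

Simulate a 60 × 60 km study (three road classes whose per-km intensity
multipliers are 0.23, 0.29 and 0.43; 17 years; seasonal, attributed
records with injected duplicates and corrupt coordinates), clean it, and
quantify the road bias for tertiary roads:

```r
library(koalasight)

scn   <- read_scenario(system.file("extdata", "example_scenario.yaml",
                                   package = "koalasight"))
study <- simulate_study(scn)

cleaned <- clean_sightings(study$records, study$window)
cleaned$report
#> <cleaning_report>
#>   input: 2541
#>   excluded bad coords/date: 25
#>   excluded non-live status: 352
#>   excluded duplicates: 50
#>   retained: 2114

rast <- study$covariates[["tertiary"]]
berman_test(cleaned$records, rast, study$window)
#> Berman Z1 test [tertiary]
#>   Z1 = -33.2657, p = 1.21e-242 (n = 2114)
#>   window covariate: mean 2.762, var 5.014

fit <- fit_loglinear_ppm(cleaned$records, rast, study$window, n_dummy = 160)
fit
#> Log-linear Poisson point-process model (Berman-Turner, 160 x 160 dummy grid)
#>   n = 2114 events; log-likelihood -2331.17; AUC 0.745
#>   alpha (log intensity at Z = 0): 0.7267
#>   beta[tertiary] = -0.7265 (se 0.0226); per-km multiplier 0.484 (51.6% decrease per km)
```

Reading: sightings sit far closer to tertiary roads than random
locations would (Z₁ strongly negative), and fitted intensity roughly
halves with each kilometre of distance. The fitted 51.6% per-km decrease
is attenuated relative to the generative tertiary multiplier (57%
decrease) because the scenario's intensity also loads on primary and
secondary roads while the model — like the analysis it reproduces — fits
one covariate at a time. `rhohat()` gives the model-free view and
`autoplot(rhohat(...), fit = fit)` overlays the parametric curve on its
confidence band; `tidy()` / `glance()` return broom-style summaries.

`run_pipeline(config, outdir)` executes every stage on a synthetic
scenario or on real input files and writes all tables, rasters,
statistics and a run manifest; `inst/cli/koalasight.R` is a thin
command-line wrapper over it.

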