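# burrowclock

Breeding phenology and winter movement of burrow-nesting seabirds from
light-level geolocator (GLS) records.

Many seabirds are *differential migrants*: individuals from the same colony
winter at very different distances from it. A long-standing prediction is
that shorter migrations buy earlier egg-laying, the strongest single
predictor of reproductive success. Testing it requires inferring, from
archival tag records alone, (i) where each bird wintered and how far that
is from its colony, and (ii) when it laid its egg. `burrowclock` implements
that inference chain for tags that record illuminance through time and
salt-water immersion (30-s conductivity samples summarised as 0–20 wet
counts per 10-min bin), plus daily 1°-grid geolocations:

* **Light phenology** — threshold twilights at 3 lx (linear-interpolated
  crossings), flagging of event pairs < 5 h apart, trend-based cleaning of
  flagged events, and burrow-occupancy days from sunsets with no sunrise in
  the following 24 h.
* **Immersion phenology** — maximal dry spells ≥ 5 h, day-level merging of
  light and immersion evidence, persistence-based incubation onset, and
  sex-specific lay-date back-calculation (males take the first incubation
  shift: male onset = lay day, female onset = lay day + 1).
* **Winter movement** — 1 Jan–28 Feb fixes, Gaussian-kernel utilization
  distribution on a local azimuthal-equidistant projection (reference
  bandwidth σ·n^(−1/6)), the 90% level-set centroid, and the haversine
  distance from colony to centroid (sphere radius 6371.0088 km).
* **Inference models** — two REML linear mixed models with Satterthwaite
  degrees of freedom and type-III tests, covariates scaled within sample:

      migration distance ~ year + sex + wintering latitude (scaled) + (1 | colony)
      lay date           ~ year + sex + migration distance (scaled)
                           + colony latitude (scaled) + (1 | colony)

  plus two-way interaction screening (drop all if every p > 0.200), the
  df = 2 likelihood-ratio test for a random migration-distance slope by
  colony, Pearson correlations, and Shapiro–Wilk residual diagnostics.
* **Synthetic data** — a generator whose defaults encode the study design
  this package is calibrated to (12 northeastern-Pacific colonies, 109
  birds with the published sex/year counts) and whose generating
  coefficients are the published model estimates, rendering each bird into
  raw light, immersion and geolocation records with known ground truth.

See `vignette("burrowclock-methods")` for the models, assumptions and
numerical choices.

## Worked example

```r
library(burrowclock)

cfg    <- simConfig(seed = 42)      # the default 12-colony, 109-bird design
cohort <- generateCohort(cfg)
recs   <- recordsFromTruth(cohort)  # truth-level one-row-per-bird table

fitDistanceModel(recs)
#> Linear mixed model (REML, Satterthwaite df): migration_distance_km, n = 109 birds, 12 colonies
#>                          term estimate    se   df       t        p
#>                    Intercept*   1449.0 250.3 11.6   5.789 9.91e-05
#>                   Year (2015)    -21.8  76.2 96.9  -0.286 7.76e-01
#>                       Sex (F)    -30.8  62.3 95.1  -0.494 6.22e-01
#>  Wintering latitude (scaled)*   -723.9  36.2 96.2 -20.022 4.40e-36
#> Random effects: colony SD = 838.7, residual SD = 302.2

fitLaydateModel(recs)
#> Linear mixed model (REML, Satterthwaite df): lay_doy, n = 109 birds, 12 colonies
#>                         term estimate   se    df       t        p
#>                   Intercept* 128.5940 1.77  19.5 72.5603 3.04e-25
#>                 Year (2015)*  -9.6118 1.55 100.6 -6.2094 1.20e-08
#>                      Sex (F)  -0.0522 1.34 101.3 -0.0389 9.69e-01
#>  Migration distance (scaled)   1.6394 1.03  93.6  1.5923 1.15e-01
#>    Colony latitude (scaled)*   5.3084 1.40  16.4  3.7798 1.58e-03
#> Random effects: colony SD = 4.1, residual SD = 6.7

lrtRandomSlope(recs)
#> Random-slope LRT: chi2 = 2.91, df = 2, p = 0.23 (REML)
```

One cohort at one seed: the recovered slopes sit near their generating
values (−723.9 ± 36.2 km per SD of wintering latitude against a generating
−708.0; +5.31 ± 1.40 days per SD of colony latitude against +5.2), the
asterisks mark p < 0.05, and the random-slope test finds no evidence that
the distance–lay-date slope varies by colony. Single-cohort estimates
scatter around truth (this seed's year effect, −9.6, is ~3 SEs from its
generating −5.1); the acceptance script below averages that scatter out
over 200 cohorts.

The sensor chain for one bird, from raw records back to its lay date:

```r
bird  <- cohort[1, ]
sched <- behaviourSchedule(bird, cfg)
light <- simulateLightSeries(bird, sched, cfg)
wet   <- simulateImmersionSeries(bird, sched, cfg)

ev    <- resolveFlagged(flagShortIntervals(detectTwilights(light)))
days  <- mergeEvidence(detectBurrowDays(ev, bird$colony_lon),
                       findDrySpells(wet), bird$colony_lon)
onset <- inferIncubationStart(days, breedingWindow = cfg$breedingWindow)
estimateLayDate(onset$doy, bird$sex, year = as.integer(bird$year))
#>   incubation_start_doy lay_doy lay_date
#>                    132     131 2014-05-11    # truth: lay_day = 131

migrationSummary(simulateWinterFixes(bird, cfg),
                 list(latitude = bird$colony_lat, longitude = bird$colony_lon))
#>   n_fixes wintering_latitude wintering_longitude migration_distance_km
#>        59           54.64             -131.28                  1051.5
```

The female's first dry/dark day is DOY 132, so her egg was laid on DOY 131
— exactly the generator's truth. The recovered centroid (54.64° N) sits on
the bird's true centroid to within a grid cell, and the 1051-km distance is
the centroid-to-colony great-circle distance.

`runAll(cfg, outDir = "out/")` chains everything — cohort, sensors,
phenology, movement, models, diagnostics, a recovery table and a manifest
with per-stage timings and file checksums — and `inst/cli/burrowclock.R`
exposes `simulate` / `run` / `models` subcommands for shell use.

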