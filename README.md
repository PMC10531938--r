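# funhab

Landscape fragmentation reshapes where a habitat-specialist insect can live
and how it moves. `funhab` is an R package for the full chain of analysis
behind that question, built for landscape and movement ecologists working
with a woodland-edge specialist butterfly and its host plant:

1. **Functional-habitat connectivity from binary land-cover rasters.**
   Matrix-edge-core classification by morphological erosion; signed
   Euclidean distances to the forest boundary; the *extended forest edge*
   (EFE) band — pixels with signed distance in a configurable interval,
   default (-86, +11) m — taken as the species' functional habitat; and
   gap-crossing *functional connectivity* (FC) maps in which every
   functional-habitat pixel carries the total area (ha) reachable by an
   organism able to cross matrix gaps up to a threshold (default 500 m),
   with per-pixel mean and CV across land-cover epochs.
2. **Occurrence and survey statistics.** Hexagonal aggregation of point
   records (observations, years, decades per cell), Welch comparison of
   edge-distance distributions, ranking of candidate sampling cells,
   spatially constrained random survey points, quadrat-level Shannon
   evenness of host-plant stems, and a linear mixed model contrasting stem
   abundance between fragmented and homogeneous woodland.
3. **Flight-arena time budgets.** Ethogram pooling into
   resting/departing/navigation, aggregation by host-plant presence with a
   `log(3)` exposure offset for the three pooled control tunnels, and three
   negative-binomial mixed models (glmmTMB, log link) culminating in the
   origin x category interaction:

   `duration ~ origin * category + (1 | trial) + (1 | id) + (1 | tunnel)`

   with Wald linear contrasts, fixed-effect marginal means and AIC
   covariate screening.

Seeded synthetic generators (`generate_landscape()`, `generate_occurrences()`,
`generate_veg_surveys()`, `generate_trials()`, direct NB simulators) emulate
every input, so the entire pipeline runs and is tested without external data.
Rasters are exchanged as plain-text Esri ASCII grids; tables as CSV.

## Worked example

```r
library(funhab)

# a fragmented synthetic woodland, 10 m pixels
L   <- generate_landscape(120, 120, p = 0.35, f = 0.15, seed = 7)
d   <- signed_edge_distance(L)
efe <- extract_efe(L, c(-86, 11), distances = d)
fc  <- functional_connectivity(efe, crossing_dist = 100)
fc
#> <fc_map> 120 x 120 pixels, 10 m resolution [fc]
#>   origin: (0, 0)  crs: local-metric
#>   values: min 0, max 94.17, NoData pixels: 0
```

Nearly all habitat here sits within the edge band (94.17 ha of EFE), and at
a 100 m crossing capability the whole mosaic fuses into one functional
cluster: a butterfly anywhere on it can reach 94.17 ha. With
`crossing_dist = 0` the same map shows individual patch areas instead.

```r
ev  <- generate_trials(trial_sim_spec(seed = 12))   # 14 butterflies, 2 trials
ana <- reproduce_time_budget(ev)
ana
#> Time-budget analysis
#>   shares of recorded time (%):
#>    resting  departing navigation
#>       88.8        5.8        5.4
#>   per-tunnel minutes:
#>    E   W   S   N
#>  228 206 205 202
#>   departing - navigation: Linear contrast: mu = 0.0149 (SE 0.122), z = 0.12, p = 0.902
ana$fits$origin_interaction$coefficients[5, c("term", "estimate", "se", "p")]
#>                                 term estimate        se            p
#> 5 originfragmented:categorydeparting 1.536871 0.2318022 3.354689e-11
```

The synthetic trials are resting-dominant (~89% of recorded time in this
cohort) and carry a true origin-by-departing log effect of 1.16; this seed
estimates it at 1.54 +/- 0.23 — butterflies of fragmented origin spend
several-fold more time in departing flight — while the contrast between the
two flight categories is indistinguishable from zero, as expected when both
are small shares of the budget.

An end-to-end run (landscape -> connectivity -> hexagonal aggregation and
site ranking -> vegetation -> behaviour), writing every product plus a JSON
manifest:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

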