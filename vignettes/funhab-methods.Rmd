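---
title: "Methods: functional habitat connectivity and flight time budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional habitat connectivity and flight time budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funhab)
```

`funhab` implements a three-part analysis linking woodland fragmentation to
butterfly movement behaviour: (1) raster workflows that map a species'
*functional habitat* and how much of it a disperser can reach, (2) occurrence
and vegetation-survey statistics used to choose and characterise sampling
sites, and (3) negative-binomial mixed models of behavioural time budgets
from flight-arena trials. This vignette explains each model, its assumptions,
the tunable parameters, and the numerical choices made where the design was
genuinely open.

## 1. From binary habitat to functional connectivity

### Matrix-edge-core classification

The input is a binary raster (1 = habitat, 0 = matrix) on a projected metric
grid, 10 m pixels by default. `classify_mac()` erodes the habitat mask
`edge_depth_px` times with a 3x3 (8-connected) structuring element —
equivalently, once with a `(2k+1)`-square box — so *core* pixels are habitat
pixels whose full Chebyshev neighbourhood of that radius is habitat; the
remaining habitat swath is *edge*. The default depth of 10 pixels renders the
conventional 100 m edge zone of temperate woodland. NoData (`NA`) propagates
and never counts as habitat: pixels bordering NoData cannot be core, a
conservative rule that slightly widens edges along masked borders.

### Signed edge distance and the extended forest edge

`signed_edge_distance()` gives each pixel the Euclidean distance (pixel
centre to pixel centre) to the nearest opposite-class pixel, negative inside
habitat. Distances are centre-to-centre rather than to a vectorised boundary:
sub-pixel edge geometry is not defined by a categorical raster, and the
centre convention is exactly checkable against an all-pairs scan (the test
suite does so). The *extended forest edge* (EFE) — the band in which a
woodland-edge specialist and its host plants actually live — is then the set
of pixels whose signed distance falls in a closed interval, by default
(-86, +11) m. That default is the interquartile range of edge distances of
the focal species' occurrence records in the source landscape; it is kept as
a constant because recomputing it requires the full occurrence database, but
`interquartile_interval()` (type-7, linear-interpolation quantiles) rebuilds
a band from any distance sample. Whether the band should instead be centred
on a 50 m edge midline is ambiguous in the field literature; the
signed-distance-about-the-boundary reading is implemented, and the interval
is fully user-configurable.

### Gap-crossing connectivity

`functional_connectivity()` merges EFE patches (8-connected components)
whose mutual Euclidean gap is at most the crossing capability `crossing_dist`
(default 500 m, a defensible mid-range flight capacity for a mid-sized
nymphalid) and assigns every EFE pixel the total EFE area, in hectares, of
its merged cluster. The merge is realised as an exact-Euclidean disc
dilation of radius `crossing_dist / 2`: pixels within that distance of the
band (computed with a distance transform, not a discrete brush) are joined
to it and 8-connected components of the dilation define the clusters. This
is mathematically the standard morphological reading of "gaps no wider than
the threshold are bridged" and, on every synthetic raster whose inter-patch
gaps avoid a +/- one-pixel-diagonal band around the threshold, it partitions
patches identically to a brute-force patch-graph oracle (pairwise minimum
pixel distances, transitive closure). Gaps inside that ~14 m band can fall
either way; this is an unavoidable property of pixel-centre discretisation,
so tests and the acceptance analysis exclude it explicitly. 8-connectivity
was chosen for patch unity (conservative: diagonal pixels belong together);
cluster values are constant by construction and cluster areas sum exactly to
the band's total area.

Per-pixel temporal summaries over land-cover epochs (`temporal_summary()`)
report the mean and the coefficient of variation, CV = sample SD (n-1
denominator; the estimator is a deliberate choice, stated here because the
quantity is reported per pixel) divided by the mean, with CV set to NoData
where the mean is zero.

### Raster I/O

Rasters travel as Esri ASCII grids (plain text) with a comment-line metadata
convention for layer, units, CRS tag and epoch. The package performs no CRS
reprojection: all inputs must share one projected metric CRS, asserted via
the tag.

## 2. Occurrences, site ranking and surveys

Occurrences are aggregated on a flat-top hexagonal grid whose `spacing` is
the distance across flats (5 km for regional screening, 1 km for
connectivity summaries). Points map to cells by exact axial cube-rounding —
the nearest-centre rule — which is deterministic including boundary points.
Per cell the package counts records, distinct years, and distinct calendar
decades (1970-1979, ...). Candidate sampling cells are ranked
lexicographically by abundance, then decades, then years (descending; ties
by cell id), and among the `top_k` best cells (default 5; the exact pool
size used in the field screening is not documented, so it is exposed as a
parameter) the cells with the lowest and highest mean connectivity become
the fragmented- and homogeneous-woodland candidates. Survey points are drawn
uniformly over a cell's EFE pixels by rejection sampling with a 200 m
minimum spacing against spatial pseudo-replication.

The host-plant survey protocol is a 20 x 20 m plot in 16 quadrats of
5 x 5 m. Spatial evenness is the quadrat-level Shannon index
`H = -sum(p_q log p_q)` in nats (0 to `log(16) ~ 2.77`); note `H` is also
bounded by the log of the plot total, which matters for sparse plots. The
field protocol stopped counting at 25 stems; the cap is applied per plot by
default (truncating in quadrat order, like a surveyor stopping mid-plot)
with a per-quadrat variant behind `cap_level` because the protocol sentence
admits both readings. The abundance contrast is a Gaussian linear mixed
model, per-quadrat stems on habitat class with a random plot intercept,
fitted by REML with Satterthwaite degrees of freedom (via lmerTest); the
Welch two-sample test (via `stats::t.test`) serves the edge-distance
comparison between species groups.

## 3. Negative-binomial mixed time budgets

Raw voice-recorded behaviours pool into three categories — *departing*
(net/sun flight, read as dispersal initiation), *navigation* (routine
within-habitat movement) and *resting* — and durations are aggregated per
butterfly, trial, tunnel and category, with explicit zeros for cells never
observed. Whole seconds are modelled as counts with a negative-binomial
GLMM, log link, dispersion estimated ("NB regression" has no link function
of its own; NB2 with log link is the standard reading), via glmmTMB. Three
variants map onto the three scientific questions:

1. `category_only`: `duration ~ category + (1|trial) + (1|id)` — do the
   behaviours differ in total time?
2. `tunnel_interaction`: on a table aggregated by host-plant presence
   (target tunnel vs the three pooled controls),
   `duration ~ tunnel_type * category + offset(log 3) + (1|trial) + (1|id)`.
   The `log(3)` offset on control rows corrects their three-fold exposure;
   simulating exact 3x control exposure and refitting recovers a null
   tunnel-type effect, which is the package's operational test that the
   offset is wired correctly.
3. `origin_interaction`: `duration ~ origin * category + (1|trial) + (1|id)
   + (1|tunnel)` — the origin-by-departing interaction is the fragmentation
   signal.

Reference levels are resting / control / homogeneous, so coefficients read
as log rate ratios against the resting baseline. Abiotic covariates
(temperature, humidity, insolation; insolation treated as an arbitrary
continuous score since its scale is instrument-specific) are available in
all variants and screened by AIC (`select_by_aic()`); trials cut short at
oviposition enter at their recorded length, with no renormalisation, because
the stopping rule is part of the protocol. Near-zero random-effect variances
are reported as estimated, not pruned — boundary fits are flagged
(`converged = FALSE`) rather than raised. Linear contrasts are Wald tests on
the fixed-effect covariance (`w' beta`, `sqrt(w' V w)`); a likelihood-based
alternative would be defensible but Wald matches the reported-contrast
convention and is exactly checkable. Marginal means exponentiate the fixed
linear predictor at offset 0 with CIs from the fixed-effect covariance only,
deliberately excluding random-effect uncertainty.

## 4. What the synthetic generators emulate

All generators are deterministic under a seed and emit exactly the formats
the analysis reads, so every stage is testable without external data.

* **Landscapes** (`generate_landscape()`): random-cluster growth to an exact
  habitat proportion; the fragmentation parameter sets seed density, from
  one compact block (`f = 0`) to scattered pixels (`f = 1`). This reproduces
  the *structural* contrast (patch size, edge density) between homogeneous
  and fragmented woodland, not any real geography, topography or land-cover
  legend. Epoch series (`generate_epoch_series()`) nibble a fixed fraction
  of habitat per epoch from patch boundaries inward, giving monotone loss.
* **Occurrences** (`generate_occurrences()`): signed edge distances follow a
  target normal (default mean -34 m, SD 106 m — records concentrated just
  inside the forest edge) by matching sampled target distances to pixels
  within one pixel of that distance; the achievable range is bounded by the
  landscape's distance range, so emulating the default regime needs a
  landscape with interiors beyond about -350 m (tests use a 4 x 4 km compact
  block). A background fraction is placed uniformly.
* **Vegetation surveys** (`generate_veg_surveys()`): plot totals are
  negative-binomial around a class mean, split over quadrats by a symmetric
  Dirichlet-multinomial; concentration `alpha` controls clumping. Defaults
  (homogeneous: mean 16 stems, `alpha = 20`; fragmented: mean 22,
  `alpha = 0.6`) reproduce the study's qualitative and approximate
  quantitative pattern — more stems but lower evenness in fragmented
  woodland (class means near 2.15 vs 1.85 nats). Under the 25-stem plot cap
  the homogeneous mean cannot reach the uniform ceiling regardless of
  `alpha`, because `H` is bounded by the log of the plot total; the reported
  field value of 2.23 nats is only attainable with larger stem totals, one
  reason the per-quadrat cap reading exists.
* **Trial logs** (`generate_trials()`): per trial, category seconds are
  Dirichlet-multinomial over the 1800 s trial (the Dirichlet stage supplies
  between-trial overdispersion), with the fragmented departing share
  multiplied by `exp(1.16)` and all shares renormalised — making the
  multiplier exactly the origin-by-departing log rate ratio. Baseline shares
  are calibrated so the expected pooled budget over the 10:4 origin mix
  matches the observed 90.9/5.1/4.0% split. Tunnel allocation prefers the
  target tunnel. What this generator does *not* emulate: serial dependence
  of behaviour within a trial, weather covariate effects (covariates are
  drawn independently of behaviour, so their AIC screen should and does drop
  them), and trial truncation at oviposition.
* **Direct NB simulators** (`simulate_timebudget_trials()` /
  `simulate_timebudget_exposure()`): draw from the count model itself, for
  parameter-recovery and offset validation where the data-generating process
  must match the fitted model exactly.

Because the generators share only the *statistical structure* of the field
data, green tests certify the algorithms and the estimators — erosion and
distance exactness, partition correctness, unbiased effect recovery,
calibrated intervals — not any property of real Walloon landscapes or real
butterflies.

## 5. Validation design and problem sizes

The test suite pins every operation to an independent oracle at sizes chosen
to keep a full run in a few minutes: brute-force erosion and all-pairs
distance scans on seeded grids up to 100 x 100; the patch-graph oracle on 50
few-patch landscapes (about 4% cover, 60 x 60) with near-threshold gaps
excluded; Welch and quantile formulas evaluated directly; emmeans as an
independent route to contrasts and marginal means. Mixed-model operating
characteristics use 200 replicates each: the exposure offset recovers a null
tunnel effect within 2 SE in well over 90% of replicates, and the
origin-by-departing effect of 1.2 is recovered with bias under 0.03 and
~95% Wald coverage, with coverage computed over the cleanly converged
replicates (boundary/singular fits — which the small random-effect SDs of
this design produce in a substantial minority of replicates, as they did in
the field data — are flagged and excluded rather than silently included).
`scripts/acceptance.R` re-derives all headline numbers from scratch at the
same sizes.

## 6. Known limitations

* Connectivity is purely geometric: no resistance surfaces, least-cost
  paths, or behavioural matrix effects; the crossing capability is a single
  isotropic distance.
* Edge distances are pixel-centre quantities; bands narrower than one pixel
  are not representable, and the (-86, +11) m default at 10 m resolution
  admits interior distances from -80 m and the first +10 m matrix ring.
* The ranking step screens occurrence cells before connectivity, so a
  high-connectivity cell with few records is never selected — intended, but
  worth remembering when the occurrence database is sparse.
* The behavioural models treat seconds as independent NB counts given the
  random effects; within-trial sequence structure (bout lengths, switching)
  is out of scope.
* With 10 + 4 butterflies the origin contrast is powered only for large
  effects; the simulators make this visible (SEs near 0.5 on the
  interaction), which mirrors the pilot nature of the field design.
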