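---
title: "Methods: simulating and estimating a National Forest Inventory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating a National Forest Inventory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfisim)
```

## Scope and model

`nfisim` implements the survey machinery of a Nordic-style National
Forest Inventory: a landscape is sampled on stratified systematic grids,
each sampled location is visited with a nested plot protocol, tree-level
observations are turned into volume, biomass and increment predictions,
and plot values are expanded to population statistics with design-based
estimators. Because national field data cannot be shipped, the package
pairs the estimation chain with a synthetic landscape generator whose
statistical structure matches what the design assumes, so that every
stage has a ground truth to be tested against.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open and the
package had to make a call.

## The sampling design

Plot locations form a square lattice with 3 km spacing. Stratum
membership follows the operational rules: outside the far-northern region
a location is lowland (stratum 1) below the alpine elevation threshold
and alpine (stratum 2) above it; alpine locations are retained only if
they fall on the 3 km × 9 km sub-lattice. In the far-northern region the
same logic separates the productive stratum 3 (3 km × 3 km) from stratum
4 on the 9 km × 9 km sub-lattice. Which of the three 3-km rows carries
the coarse sub-lattice is a configuration (`phase`, default 0), since it
is a property of the national grid rather than something inferable.

Sampling weights are 9, 27, 9 and 81 km² per plot. The fourth weight is
stored as the exact planar lattice cell 9 km × 9 km = 81 km² rather than
the approximate real-world value 82 km², because on the package's planar
synthetic geometry 81 is the value that makes area expansion exactly
self-consistent; real-data users can override the weight table
(`stratum_definitions(weights = ...)`).

Panels: the landscape is tessellated into 45 km Latin squares of 5 × 5
blocks of 9 km. The panel of the block at global block indices `(i, j)`
is `((i + 2j) mod 5) + 1`. This cyclic assignment is a Latin square
within every 45 km tile, repeats identically across tiles, and — because
horizontal neighbours differ by 2 (mod 5) and vertical neighbours by 1 —
no two edge-adjacent blocks anywhere share a panel. The national pattern
is not published beyond these properties, so the cyclic square is the
package's choice; any layout with the same two properties would do, and
the test suite asserts the properties, not the layout.

Grid origin: for design simulations the lattice origin is drawn uniformly
within one 3 km cell. A fixed national grid admits no repeated-sampling
argument on a single landscape; randomizing the origin makes
design-unbiasedness an empirically testable statement, and the test suite
exercises it with replicated estimates over random origins. Real-data
mode accepts a fixed origin.

The stratum map is produced by universal kriging of the plot-level alpine
indicator with a linear trend in logit-transformed elevation under a
spherical variogram with zero nugget, sill 0.73 and range 5600 m. The
kriging system is solved densely with all observations up to 2,000 plots
and with the 500 nearest observations beyond that; the dense solve
preserves exact interpolation at data points (with zero nugget), which
the tests assert. Duplicate observation locations are averaged before
assembly. Predictions are clipped to [0, 1] and thresholded at 0.5.

## The field protocol

All nested units derive their radii from `sqrt(area/pi)`: 250 m² tree
plot (8.92 m), 0.1 ha stand plot, 0.2 ha habitat plot, five 16 m²
regeneration subplots (2.26 m; center and 12 m in the cardinal
directions), four 5.3 m² small-tree subplots and four 0.25 m² berry
quadrats at 5 m, two 18 m transects, and a 100 m² dropping-count plot.
Boundary conventions are inclusive: a tree at exactly 8.92 m distance or
exactly 5.00 cm dbh is tallied (the caliper threshold is "≥ 5 cm").

Plot splitting uses a straight chord as the stand boundary. Field crews
follow irregular stand borders, but a chord keeps part areas in closed
form (circular segments) while exercising the same logic: a split
requires both parts to reach 37.5 m² (15 % of the plot) *and* the stands
to differ in land use, maturity class, site index class, or growing
stock (relative difference above a configurable 50 %).

Height-tree selection: if at most 10 trees stand on the plot, all are
height-measured. Otherwise trees are selected by angle count with
inclusion limit `dbh(cm) · 0.5/√BAF` metres. The BAF is the smallest
value of the ladder 0.5, 1, 2, 3, 4, 6, 9 m²/ha whose expected count —
evaluated on the previous visit's stems when available, else on the
current tally (the results are identical, only the field order differs)
— does not exceed 10. The ladder and the expected-count rule are package
choices; operationally the BAF is "determined by the previous
measurements", which any such rule satisfies. The selection probability
of tree *i* under a uniformly random position in the plot is
`min(1, (limit_i/R)²)`, proportional to basal area until capped at 1;
this is the probability whose inverse weights the correction factors.

Key habitats are classified by density thresholds on per-hectare counts
over the 0.2 ha plot, with distance chaining (union–find over pairwise
distances; order-independent by construction) and regional variants
(e.g. 60 instead of 20 nutrient-bark trees per ha, and 15 m instead of
25 m chaining, in the west/north). Which regions take the 15 m variant is
not fully specified operationally; the package ties it to the same
west/north flag as the density variant and leaves both as configuration.
A category whose discriminating attribute was not recorded (lichen
flags) is reported as *not assessed*, never as absent. The ≥ 0.2 ha
extent rule cannot be evaluated from inside the plot; it is taken from a
stand attribute of the simulated landscape.

## The dendrometric chain

Functional families (stand-ins; coefficients loadable from YAML):

* height: `h = 1.3 + (d/(a + b·d))³` m, d in cm — monotone, with
  asymptote `1.3 + b⁻³`;
* volume: `v = (c₁·d²·h + c₂·d²)/1000` m³ — strictly increasing in `h`,
  which guarantees a unique height back-solve;
* biomass: `ln B = c₀ + c₁·d/(d + k)` kg.

The published Norwegian/Swedish coefficient tables are deliberately not
reproduced; every package-level computation (correction factors,
back-solving, increment, the estimators) is allometry-agnostic, and the
tests assert ratios, round trips and simulation truths rather than
absolute volumes.

Species routing: Sitka spruce has its own volume function; other spruces
and firs use the spruce function; all remaining conifers use the pine
function; all broadleaves use the birch-type function. Biomass routes
conifers and broadleaves to separate sets.

Correction factors are computed per plot and species group as
`Σ wᵢ v(dᵢ, hᵢ_measured) / Σ wᵢ v(dᵢ, hᵢ_approx)` over the h-trees, with
`wᵢ = 1/πᵢ` (uniform when all trees were measured). With inverse-
probability weights an equal height perturbation moves the factor by the
same absolute amount for a small as for a large tree — i.e. small trees
gain influence relative to the volume-proportional uniform weighting,
which is the intent of the weighting. Groups without h-trees take
fallback factors keyed by maturity group, site index class, species and
region. Unmeasured trees get `v = factor × v(d, h_approx)` and a final
height back-solved from that volume (bracketed root search, volume
tolerance 1e-6 m³).

Breakage: the stem is treated as a cone tapering linearly from dbh to
zero at the top, so a break at relative height `p` removes the fraction
`(1 − p)³` of the stem volume; the adjustment applies only when the
diameter at the break, `dbh·(1 − p)`, is at least 10 cm. The correction
factor is applied before the breakage reduction (the order is not
specified operationally; applying the plot-level height calibration to
the intact stem first is the self-consistent choice). The rule is
config-switchable.

Growing seasons: with a 100-day season starting on day-of-year 152
(1 June, configurable; only differences matter), the number of growing
seasons between two visits is the whole calendar years elapsed plus the
difference of the clamped within-season day counts divided by 100. Over
a 5-year cycle this spans exactly [4.00, 6.00], which the acceptance
script recomputes by exhaustive search over all date pairs.

Increment: the dbh one year before the current visit is interpolated as
`dbh_curr − (dbh_curr − dbh_prev)/seasons`; its volume is predicted under
the previous cycle's height relationship (approximated height times the
previous correction factor), and the annual increment is the difference
from the current volume. Ingrowth takes the mean annual dbh difference of
matched trees in the cell (species, 5 cm diameter class, maturity group
young = classes 1–3 / old = 4–5, site index class), widening empty cells
by dropping site index, then the maturity group, then the diameter
class, then species. Removal volume adds 2.5 years of the previous
annual increment to the previous volume (removals are on average
mid-cycle).

Maturity classes use a site-index dependent entry-age table, shared
across species by default (per-species tables can be supplied): class 3
entries run 55→15 years from the poorest to the best site, class 4
90→25, class 5 120→40, spanning the published class ranges while keeping
the class monotone in site index at fixed age; the table is audited
exhaustively by the tests. The published class ranges overlap across
species and sites; the table *is* the package's explicit resolution of
that overlap. H40 site index classes 6–26 are assigned by nearest class
value with half-open 3 m bins (class 14 covers [12.5, 15.5) m); the
exact class ladder varies by species in practice and is configurable.

## Estimators

Expansion total: `T̂ = Σ_h w_h · 100 · Σ_{i∈h} yᵢ` for per-hectare plot
values `yᵢ` (the factor 100 converts km² to ha). Variance uses the
within-stratum sample variance under a simple-random-sampling assumption
— deliberately conservative for a systematic design — without finite
population correction; strata with a single plot are collapsed into the
nearest-id stratum for variance only. Domain estimates use
indicator-multiplied values, which makes them exactly additive over
domain partitions. Stratum areas default to the self-consistent
`n_h · w_h`; official areas override. Reserve-densification plots are
flagged and excluded from national expansion by default (their weights
are not published; exclusion is the conservative choice).

Line-intersect deadwood volume per plot: `v̂ = π²/(8L) · Σ dᵢ² · 10⁴`
m³/ha with intersection diameters in m and the recorded transect length
`L` (36 m unless truncated; zero-length plots are excluded with a
warning). Standing dead trees additionally flow through the ordinary
plot expansion path via their tree records, so both assessment routes
are available and labeled.

Synthetic harvest: per region, `utilization × Σ volume/ha × cell area`
over change-mask cells, with the changed cells zeroed in the returned
volume raster; utilization defaults to 0.8 (20 % of standing volume is
assumed left in the forest). Regions can be an id raster or polygons
(rasterised by cell-center point-in-polygon).

## The synthetic landscape generator

The generator's job is to realise the structure the design assumes, with
published quantities as calibration targets:

* Elevation is a Gaussian random field with the stratum-map variogram
  (zero nugget, sill 0.73, range 5600 m) on the logit scale, mapped to
  (0, 1500) m by `1500 · plogis(z)`. The inverse-logit scale and upper
  bound are package choices (the operational covariate is logit-
  transformed elevation, but the inverse map is not published); the
  latent field is exactly recoverable as `qlogis(elev/1500)`, which is
  what the variogram-recovery tests fit.
* Stands are a Voronoi partition of Poisson seed points, realised as
  nearest-seed assignment on a 25 m working lattice (no polygon geometry
  is needed downstream; stand areas come from lattice cell counts).
  Stand geometry is not specified by any source; Voronoi cells are
  simple, space-filling and size-controllable via the seed density.
* Each stand draws a stratum from its elevation (and region), a land use
  (forest probabilities per stratum default to the published forest
  shares 66.4/9.5/80.0/20.5 %), a dominant group from the published
  per-stratum species mixes (e.g. 0/4.2/94.9/0.8 % in stratum 4), a site
  index that worsens with elevation, and an age; the maturity class
  follows from the entry-age table. Individual trees follow the dominant
  group with 90 % fidelity, reproducing "dominant species" logic at the
  stand level.
* Tree positions are homogeneous Poisson within stands (within-stand
  clustering is not modelled — the spatial pattern of stems within
  stands is unspecified in any source, and Poisson is the neutral
  choice). Diameters are 5 cm plus a Weibull excess per maturity class;
  heights follow the h–dbh curve with lognormal deviations whose
  residuals persist through remeasurement, so measured and approximated
  heights differ realistically and correction factors are exercised away
  from 1.
* Dynamics: per growing season each survivor adds a Gaussian dbh
  increment (mean 0.3 cm, sd 0.1 cm); annual mortality 0.005; stand-level
  harvest probability 0.05 per 5 years (all stems removed, age reset);
  ingrowth arrives at the caliper threshold at 5 stems/ha/yr. Tree
  identities are conserved: survivors + dead + removed partition the
  previous live list, survivors + ingrowth form the new one, and the
  tests assert exactly that.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: climate- and competition-driven growth,
spatially correlated mortality and windthrow, irregular stand borders,
within-stand clustering, measurement error in dbh/height/positions, and
GNSS error. Estimator unbiasedness shown here is design-unbiasedness
under the randomized grid on landscapes with the configured structure,
not a statement about model error in real inventories.

## Numerical choices and problem sizes

* Gaussian fields are simulated by dense Cholesky factorisation; above
  4,000 nodes the field is simulated on a coarsened lattice and
  bilinearly refined. At native resolution the field is drawn directly
  at cell centers — resampling from an offset lattice would smooth the
  field and bias the sill downward.
* The spherical variogram is fitted by profiled weighted least squares:
  for a fixed range the nugget and partial sill are a non-negative
  linear least-squares problem solved in closed form; the range is found
  on a 250-point log grid with local refinement. This avoids the local
  optima that plague joint three-parameter descent and recovers
  noiseless curves to solver precision.
* Height back-solving brackets the root and requires the volume to match
  to 1e-6 m³; the round trip is tested to better than 1 mm.
* Circular-segment part areas are closed-form and are verified against
  Monte-Carlo point-in-segment integration.
* Test and acceptance simulations are sized for a laptop-class single
  core: variogram recovery uses 50 realizations of a 3 km lattice over
  60 km × 60 km; design-unbiasedness uses 200 random grid origins on a
  24 km landscape; the line-intersect check uses 250–300 random plots
  against a 400-log population on a 4 ha torus. These sizes put the
  Monte-Carlo error well below the asserted tolerances.

## Known limitations

* Real-data mode consumes the same plain-text formats the package writes
  (CSV tables with a schema sidecar, ESRI ASCII rasters, GeoJSON,
  YAML); GeoTIFF/shapefile inputs must be converted externally.
* The correction-factor fallback table and the regional habitat variants
  ship empty/default — they are containers for operational values the
  package cannot know.
* Variance estimation is the conservative SRS form throughout; no
  model-assisted or model-based alternatives are implemented.
* County-level estimation from pooled permanent and temporary plots is
  reduced to a hook (a combined frame), as the operational weighting is
  unpublished.
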