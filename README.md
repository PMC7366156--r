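# nfisim

Simulation and design-based estimation for a Nordic-style National Forest
Inventory (NFI), modelled on the present-day Norwegian design.

National forest statistics — forest area, growing stock, increment,
deadwood, biodiversity indicators — are produced by measuring a sparse
permanent sample of field plots and expanding the plot observations to the
population with known sampling weights. The survey machinery behind such
numbers (stratified systematic grids, panel rotation, nested plot
protocols, allometric prediction chains, expansion estimators) is usually
locked inside national agencies and is hard to test. `nfisim` implements
that machinery end to end as an open, testable R package, together with a
synthetic landscape generator, so every stage can be exercised and
verified without any field data.

## What is implemented

**Sampling design.** Plot locations on a 3 km × 3 km lattice, thinned to
3 km × 9 km in low-productive alpine terrain and 9 km × 9 km in the
far-northern stratum; per-plot sampling weights of 9 / 27 / 9 / 81 km²;
tessellation into 45 km Latin squares of 5 × 5 blocks (81 km², nine plots
each) assigning each block to one of five annual measurement panels such
that no edge-adjacent blocks share a panel; a 1.5 km densification of the
grid inside forest reserves; and a kriged stratum map — universal kriging
of the plot-level alpine indicator with a linear trend in logit-
transformed elevation under a spherical variogram (zero nugget, sill
0.73, range 5600 m).

**Field protocol.** The nested permanent plot: trees with dbh ≥ 5 cm on
250 m² (radius 8.92 m) with polar coordinates; plot splitting at stand
borders into at most two circular-segment parts of ≥ 37.5 m²; a
height-measured subsample of about 10 trees per plot selected by angle
count (inclusion limit `dbh · 50/√BAF`, BAF chosen from a fixed ladder);
regeneration, small-tree and berry subplots; two 18 m deadwood transects;
and woodland key-habitat classification by density thresholds with
distance chaining.

**Dendrometry.** Height approximation from h–dbh curves; volume from
allometric functions with plot-level correction factors (ratio of
measured-height to approximated-height volume sums, inverse-probability
weighted); heights of unmeasured trees back-solved from the corrected
volume; species routing (Sitka spruce separate, firs to spruce, other
conifers to pine, broadleaves to birch functions); biomass; growing
seasons (100-day season; 4.00–6.00 seasons per 5-year cycle); annual
volume increment via dbh interpolation one year back; removal volume as
previous volume plus 2.5 years of previous increment; H40 site index
classes; basal-area weighted stand age; a maturity-class system with
site-index dependent entry ages.

**Estimation.** Stratified expansion totals and proportions with
conservative simple-random-sampling variances; line-intersect deadwood
volume `v̂ = π²/(8L) · Σ dᵢ² · 10⁴` (m³/ha); synthetic small-area harvest
estimates by aggregating a volume raster over change-mask cells with 80 %
utilization.

**Synthetic landscapes.** Gaussian-random-field elevation (spherical
variogram, logistic back-transform), Voronoi stands with stratum, land
use, dominant species (calibrated to the published per-stratum mixes),
site index, age and maturity class; Poisson tree positions with Weibull
diameters; downed deadwood; and remeasurement dynamics (growth, mortality,
stand harvest, ingrowth) that conserve tree identities.

The allometric coefficient sets shipped with the package are documented
stand-ins of the correct functional families (the published Norwegian and
Swedish coefficient tables are not redistributed); any coefficient file of
the same shape can be dropped in via `read_allometry()`.

## Worked example

```r
library(nfisim)

cfg <- landscape_config(extent = c(0, 1000, 0, 1000), cell_size = 100,
                        alpine_threshold = 1200, seed = 42)
landscape <- simulate_landscape(cfg)
landscape
#> <nfi_landscape> epoch 2020, 1 km x 1 km
#>   24 stands (12 forest), 35503 trees (34452 live), 327 deadwood pieces

# measure one permanent plot and run the volume chain
f <- subset(landscape$stands, land_use == "forest" & maturity_class >= 4)
bundle <- measure_plot(landscape, c(f$seed_x[1], f$seed_y[1]))
bundle <- predict_plot_volumes(bundle)
bundle$corrections
#>   species_group   factor n_h source
#> 1     deciduous 1.002879   7   plot
round(summarise_plot(bundle), 2)
#>   forest volume_m3_ha agb_kg_ha deadwood_m3_ha n_trees
#> 1      1       163.32  103042.3              0      13
```

The plot holds 14 standing trees; 7 were height-measured (h-trees), and
the ratio of their measured-height volumes to their approximated-height
volumes gives the correction factor 1.0029 applied to every unmeasured
deciduous tree before its height is back-solved from the corrected
volume. Live-tree volume expands to 163 m³/ha on this plot.

A full inventory — simulate, lay out the sample, measure every plot,
estimate — runs as one pipeline:

```r
cfg <- landscape_config(extent = c(0, 9000, 0, 9000), cell_size = 300,
                        alpine_threshold = 850, stand_density = 4,
                        stems_per_ha = c(20, 120, 150, 120, 80), seed = 17)
out <- run_pipeline(cfg, "nfi-demo")
out$estimates
#>                 domain  estimator  estimate        se n_plots units
#> 1    forest area share proportion 3.333e+01 1.054e+01       8     %
#> 2     forest area (ha)  expansion 3.600e+03 1.138e+03       8    ha
#> 3 growing stock volume  expansion 8.634e+04 4.282e+04       8    m3
#> 4      downed deadwood        lis 7.141e-01 7.141e-01       8 m3/ha
```

Eight sampled plots on the randomized 3 km grid estimate a 33.3 % forest
share (SE 10.5 percentage points), 3600 ha of forest and 86 300 m³ of
growing stock for this 81 km² synthetic landscape; standard errors use the
conservative simple-random-sampling variance within strata. Every stage
writes plain-text artifacts (CSV + schema, ESRI ASCII rasters, GeoJSON,
YAML) under the output directory, with a manifest that makes reruns
bit-identical and resumable. A thin command-line front end is installed
under `inst/scripts/nfi.R`.

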