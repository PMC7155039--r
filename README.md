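# endowater

Surface-water trend analysis for endorheic (closed-basin) watersheds from
multispectral satellite imagery.

Terminal lakes and their fringing wetlands integrate the water balance of
the closed basins that feed them — runoff and precipitation in,
evaporation and human withdrawals out — and in the arid interior of
western North America they carry a continental waterbird flyway. This
package implements, end to end and fully offline-testable, the analysis
chain used to monitor such systems over a multi-decade Landsat-style
record (1984–2018, one 6-month seasonal composite per year, 2012
missing):

* **Spectral mixture analysis.** Per-pixel endmember fractions
  $f = \arg\min_{f \ge 0,\ \sum f = 1} \lVert s - Mf \rVert_2$ (fully
  constrained least squares, Lawson–Hanson NNLS with a weighted
  sum-to-one row), against a 4-endmember library (water, wetland
  vegetation, upland, alkali soil) trained per composite from NDWI/NDVI
  percentile masks and static plots.
* **Area accounting.** Fraction maps clipped to functional polygons;
  pixels with water fraction ≥ 0.10 count their full 900 m²; reservoirs,
  evaporation ponds and livestock ponds are excluded by class. Irrigated
  extent from annual maximum NDVI > 0.4 within field polygons;
  population by natural-spline interpolation of sparse census anchors.
* **Two-period change statistics.** P1 (1984–1999) vs P2 (2000–2018)
  means, SDs, Wilcoxon rank-sum tests (exact by enumeration for small
  samples, tie/continuity-corrected normal otherwise), OLS trends,
  half-away-from-zero integer percent differences, per-lake change
  vectors in (proportion-of-max mean, variance) space, and regional
  rollups.
* **Driver attribution.** Regression random forest (implemented in
  compiled code: bootstrap trees, random per-split predictor subsets,
  OOB bookkeeping) with Breiman–Cutler permutation variable importance
  and subsampling confidence intervals, ranking climate (ET, PR, RO,
  SWE; water-year aligned) against human water use (irrigated fraction,
  population density).
* **Synthetic watersheds.** `simulate_series()` generates a full
  64×64-pixel watershed — terminal lake on an alkali playa, peripheral
  and upland wetlands, irrigated fields, an excluded reservoir — with
  coupled climate/human predictor series under a snowmelt regime
  (strong linear lake decline, modest variance) or a monsoonal regime
  (stable mean, high variance, no snow), so every stage above can be
  verified against known truth.

## Worked example

```r
library(endowater)

params <- regime_params("snowmelt", seed = 1)   # the stated synthetic world
bundle <- simulate_series(params)               # 34 scenes, truth, covariates
series <- run_pipeline(bundle)                  # composite -> endmembers ->
                                                # FCLS -> polygon accounting

lake <- subset(series$water, class == "lake")
period_summary(lake$year, lake$area_ha, variable = "lake_ha")
#> <period_summary> lake_ha P1 44.2 (sd 5.04, n=16) -> P2 26.02 (sd 7.54, n=18)
#>   change -18.19 (-41%), Wilcoxon p=1.49e-06, slope -0.9833 (p=8.12e-13)
```

The synthetic snowmelt lake loses 41% of its inundated hectares between
periods (P1 mean 44.2 ha on the desk-scale 64×64 grid; n = 18 in P2
because 2012 is a flagged gap), the Wilcoxon test rejects equality of
the periods and the 35-year OLS trend is −0.98 ha/yr — the
strong-linear-decline signature the snowmelt regime states. Driver
attribution on the wetland class recovers the generator's coupling
(wetland area responds to irrigation alone):

```r
tb <- truth_design(bundle, "wetland")
permutation_vimp(fit_forest(tb, n_trees = 5000, seed = 1))
#>        predictor        vimp   se_trees rank
#> 1             ET  1.01162694 0.06498123    3
#> 2             PR -0.22893601 0.05005221    6
#> 3             RO -0.08359345 0.03950224    5
#> 4            SWE  0.13154897 0.05252501    4
#> 5 irrigated_frac 10.76637806 0.15414253    1
#> 6    density_km2  3.52493863 0.10102370    2
```

Irrigated fraction carries three times the importance of every other
predictor combined — importance being the increase in out-of-bag squared
error (ha²) when the predictor is permuted — with the climate terms and
SWE near zero, as constructed.

## Layout

```
R/                  implementation (synthetic worlds, endmembers, FCLS,
                    accounting, change statistics, attribution, pipeline)
src/                compiled FCLS solver and regression forest
tests/testthat/     unit + property + acceptance suites, with independent
                    brute-force oracles in helper-oracles.R
scripts/acceptance.R  the acceptance report
vignettes/          methods vignette: models, assumptions, design choices
inst/cli/           command-line front end (unmix / account / change /
                    attribute) over serialized bundles
```
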