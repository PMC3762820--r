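---
title: "Quantifying four centuries of forest compositional change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying four centuries of forest compositional change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestshift)
```

## The problem

Colonial land surveyors in the northeastern United States recorded
"witness trees" to mark lot corners. Pooled within a proprietary town
(roughly 100 km^2), those records are an inadvertent sample of forest
composition at the time of European colonization. Modern forest-inventory
programs sample the same landscape with clustered fixed-radius plots.
`forestshift` implements the complete comparison pipeline: deciding which
towns are adequately sampled in both eras, measuring per-town compositional
change, asking whether change is spatially structured, whether the regional
flora has homogenized, whether composition has decoupled from climate, and
which land-use covariates best explain the change.

Because both data sources identify trees inconsistently below the genus
level, all records are binned into 24 genus-level taxon groups
(`taxon_codes()`) before any comparison. Relative abundance in a town and
era is the pooled stem proportion over all retained trees; pooling (rather
than averaging per-plot proportions) keeps the plot-less witness-tree era
and the plot-structured modern era on the same footing.

## Record filters

Modern inventory data are screened before use: plots must be classed
`Forest` and hold at least 10 trees with dbh >= 12.5 cm; all retained trees
must themselves be >= 12.5 cm (the witness-tree record under-represents
small stems, so the modern record is truncated to match); and towns need at
least two qualifying plots. The diameter bound is closed (a 12.5 cm tree is
kept) — the filter language "excluded all trees < 12.5 cm" is only
consistent with a single closed threshold, and stating it exactly makes the
boundary testable. `filter_modern()` is idempotent and logs every exclusion
with a reason code; the count funnel is carried into the pipeline manifest
because the sequence of exclusions is the reproducibility backbone of any
re-analysis.

## Sampling adequacy

Whether a town's data capture its compositional diversity is decided by a
bootstrap saturation analysis (`bootstrap_curve()`, `fit_mm()`,
`ecoregion_thresholds()`):

1. Within each ecoregion, take the most densely sampled towns — at least 5
   plots (or 100 witness trees) and within the upper tercile of sampling
   density. The tercile is computed within the ecoregion, consistent with
   the ecoregion stratification of the rest of the procedure, and the
   boundary is closed.
2. For each such town, draw 100 bootstrap sets. A set contains one sample
   of n units for every n from 1 to the town's total, drawn with
   replacement; witness trees are first partitioned at random into bins of
   20 (bins are re-randomized every set, and the leftover `count mod 20`
   trees are dropped for that set).
3. Each sample's pooled composition is compared to the full-town
   composition by Sorensen *similarity* (one minus the Sorensen distance;
   the distance is what the change metrics use, the similarity is what
   saturates).
4. A Michaelis-Menten curve `y = S_max * n / (k + n)` is fit per set. The
   fit is through the origin, which buys an analytic identity: similarity
   reaches 90 % of `S_max` exactly at `n = 9k`, so the minimum adequate
   unit count is `9k` (more generally `k * p / (1 - p)`). This identity is
   asserted for every converged fit in the test suite. Non-convergent or
   degenerate fits (flat or decreasing curves) are flagged and excluded
   from averaging rather than silently kept.
5. Unit counts convert to densities through the town's polygon area; the
   per-set densities are averaged over the 100 sets, then over eligible
   towns, giving one threshold per ecoregion per era.

A town enters the analysis only if it meets both of its ecoregion's
thresholds; towns exactly at a threshold are included.

## Change metrics and tests

The abundance-based Sorensen distance
`S = sum(|x_i - y_i|) / sum(x_i + y_i)` is 0 for identical composition and
1 for disjoint taxa; on relative abundances it is half the L1 distance
(identical to Bray-Curtis on proportions). It is a semimetric — the
triangle inequality is not guaranteed and never relied upon.

Per-taxon era differences are tested with a paired Monte Carlo test: the
statistic is `|mean(pre - mod)|` and the null flips each pair's labels
independently with probability one half. The published description of the
test does not pin down the statistic; the absolute mean difference is the
simplest two-sided choice and is documented here as ours. P-values use the
add-one convention `(1 + exceedances) / (1 + n_rand)`, so zero p-values
cannot occur. No multiple-testing correction is applied across the 24 taxa
of the abundance table — each row is reported as a separate test, and
readers should interpret the table accordingly. Ecoregion comparisons use
the analogous label-shuffling permutation test (`group_permutation()`).

Beta diversity follows the town-to-town approach: each town's mean Sorensen
dissimilarity to all other towns in scope, per era. A modern mean below the
pre-colonial mean is the signature of biotic homogenization.

## Spatial structure

Geographic distances are great-circle (haversine, radius 6371 km) between
town centroids — over an eight-degree latitudinal span planar
approximations drift. Moran's I correlograms use binary weights on
half-open distance classes `[lower, upper)` and permutation tests
(two-sided, reported against the configured alpha). Mantel tests correlate
upper-triangle entries and permute rows and columns of one matrix jointly;
Mantel correlograms negate the raw correlation with the class-membership
matrix so that a positive statistic means "towns in this class are more
similar than expected", and apply a plain Bonferroni correction across the
evaluated classes (not the progressive variant sometimes used) because the
source analysis states a Bonferroni-corrected alpha of 0.05. Both
correlograms stop at half the maximum inter-town distance by default, an
edge-effect guard, and both are configurable.

Two documented ambiguities are surfaced as parameters rather than silently
resolved: the published text uses 15 km distance classes while a figure
caption says 20 km (the class width is a parameter, default 15; synthetic
landscapes use 80 km because their towns sit on a coarser grid), and the
text tests at alpha = 0.05 while the same figure marks P < 0.01 (the alpha
is a parameter and raw p-values are always reported).

## Ordination

Compositions of both eras are stacked, Wisconsin double-standardized
(columns by maxima, then rows by totals), converted to Sorensen distances,
and ordinated by NMDS. The NMDS engine is vegan's `monoMDS` (the same
engine the original analysis used through `metaMDS`), run from 50 random
starts with the best solution kept; the configuration is centered and
PC-rotated so axis 1 carries maximal variance. Half-change scaling is
omitted: it is a presentation-only rescaling and the quantities read off
the ordination (stress, era separation) are invariant to it. Era
separation is reported on the axis that maximizes the standardized
between-era mean difference — the data-chosen axis — rather than asserting
that it is "axis 2" of any particular fitted configuration; its sign is
fixed so the pre-colonial mean is negative.

Environmental vectors are least-squares regressions of each covariate on
the ordination axes (direction cosines, R^2, permutation p). The
implementation is the package's own and is cross-checked against vegan's
`envfit` in the tests.

## Drivers of change

`fit_change_tree()` is a deliberately simplified conditional-inference
regression tree: at each node the predictor-response association is
`|Pearson correlation|` with a Monte Carlo permutation p-value, Bonferroni
adjusted across predictors; a node splits only if the smallest adjusted p
is below alpha, so the tree needs no pruning. The winning predictor is cut
at the point maximizing the standardized two-sample mean difference with
at least `min_node` (default 20) rows per side, reported as the midpoint
between adjacent observed values; ties route left (`<=` goes left). This
is a linear-statistic approximation of the full conditional-inference
machinery (no quadratic forms, no ordinal/categorical support); the
published analysis does not state its minimum node size or permutation
count, so the defaults (20 and 9999) are ours, chosen so that a five-split
tree on ~700 towns is reachable.

## The synthetic landscape generator

`simulate_landscape()` builds landscapes with known ground truth so that
every downstream stage can be validated end to end:

* Towns sit on a grid spanning seven degrees of latitude; each town is a
  ~10 x 10 km square (about the 100 km^2 of real proprietary towns), so
  sampling densities are on a realistic scale. Growing degree days decline
  linearly with latitude from 4600 to 2000, and four equal-width
  latitudinal bands play the role of ecoregions.
* Taxa respond to temperature through Gaussian niches (optimum, width,
  peak). The defaults place oak/hickory/chestnut in the warm south, a
  beech-maple-hemlock belt in the middle, spruce/fir in the north — the
  simplest mechanism that produces the temperature-composition coupling
  the Mantel analysis measures. All parameters live in `sim_config()`, not
  in code.
* The era-shift operator multiplies each taxon's abundance by
  `max(0, a + b * agri)` and renormalizes, where `agri` is the town's peak
  agricultural proportion. Defaults: chestnut multiplier 0 (extirpation),
  beech/hemlock/oak declining with clearing, maple/cherry/poplar/birch
  rising with it. This reproduces the qualitative Table-3-style pattern
  (maple up ~20 points, beech down ~10-15, chestnut to zero) and makes
  compositional change causally tied to the land-use covariate.
* Peak agriculture is a logit-scale sum of a weak latitudinal trend, a
  smooth low-frequency random field, and town-level noise. The field is
  the load-bearing choice: it makes land-use history (hence change)
  spatially clustered at short lags while keeping it only partially
  aligned with climate, which is what lets the era shift *weaken* the
  temperature-composition coupling instead of reinforcing it.
* Witness trees are multinomial draws from the pre-colonial profile
  (default mean 250 per town, floor 120 — comparable to the ~252 per town
  of the real final sample). Inventory plots draw a plot-level profile
  from a Dirichlet centered on the modern profile (concentration
  `theta = 25`, emulating within-town clustering of the plot design) and
  then a multinomial of trees (default mean 36 per plot, 6 plots per
  town). Diameters are drawn above 12.5 cm so the record filters pass by
  construction unless a test configures otherwise.
* Everything is driven by one seed; the generator writes byte-identical
  CSV/GeoJSON under a fixed seed.

What the generator deliberately does not emulate: surveyor species bias,
tree-size structure beyond the filter threshold, succession through time,
and irregular town shapes. Passing the end-to-end tests therefore shows
that the pipeline recovers known structure of this kind from realistic
sample sizes — not that the historical record is free of the biases the
original data carry.

## Numerical choices and degenerate inputs

* Composition rows must sum to 1 within 1e-9; zero-tree towns are excluded
  and logged, never silently imputed.
* Unknown species names map to an explicit `UNBINNED` flag and are
  excluded with a logged count.
* Michaelis-Menten fits use `nls` with the `SSmicmen` self-start and fall
  back to Levenberg-Marquardt (`minpack.lm`); failures are flagged, and
  flagged fits are excluded from threshold averaging.
* Permutation p-values everywhere use the add-one convention; permutation
  counts must respect the implied resolution (the tree fitter refuses
  `n_perm < 99`).
* Constant responses, all-equal dissimilarities, zero-variance distance
  triangles, and empty correlogram classes are all explicit errors or
  flagged missing values, not NaNs.
* Test and acceptance problem sizes (60-town landscapes, 100 bootstrap
  sets, 999-9999 permutations) were chosen as the smallest sizes at which
  the planted effects are comfortably detectable; they are stated here as
  the package's validation conditions.

## Limitations

The dataset-scale headline numbers of the original regional analysis
depend on its archived town tables and restricted plot coordinates; this
package validates the methods against synthetic ground truth and exposes
the pipeline to run on such data when available (`load_dataset()` accepts
either the full or the screened town set). The conditional-inference tree
is an approximation, documented above. Mantel correlogram classes beyond
half the maximum distance are unreliable and excluded by default.
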