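# forestshift

Tools for quantifying centuries of forest compositional change by
comparing **pre-colonial witness-tree records** to **modern
forest-inventory plot data** at the town scale.

Colonial land surveyors marked lot corners with "witness trees",
inadvertently sampling the forest that existed at European colonization.
Modern inventory programs (clustered fixed-radius plots) sample the same
landscape today. Comparing the two eras raises a chain of methodological
questions that this package answers as tested, reusable components:

* **Which towns are usable?** A bootstrap saturation screen: Sorensen
  similarity between subsamples and the full town is fit with a
  Michaelis-Menten curve `y = S_max * n / (k + n)`; the minimum adequate
  sample is the density at 90 % of the asymptote, which for the
  through-origin model is exactly `n = 9k`. Thresholds are estimated per
  ecoregion from the most densely sampled towns and applied to all.
* **How much did each town change?** The abundance-based Sorensen
  distance `S = sum|x_i - y_i| / sum(x_i + y_i)` between a town's two
  eras, with paired Monte Carlo tests for per-taxon shifts and
  permutation tests between ecoregions.
* **Is change spatially structured?** Moran's I correlograms of per-town
  change and Mantel correlograms of composition against distance classes.
* **Has the flora homogenized?** Town-to-town mean dissimilarity
  (beta diversity) per era.
* **Is composition still coupled to climate?** Mantel correlations
  between composition distances and covariate distances, per era.
* **What drives change?** NMDS ordination with fitted environment
  vectors, and a permutation-based conditional-inference regression tree
  over land-use and biophysical covariates.
* **Does the pipeline actually work?** A synthetic-landscape generator
  (`simulate_landscape()`) with Gaussian temperature niches, a
  configurable era-shift operator (chestnut extirpation, clearing-driven
  beech decline and maple rise), and known ground truth for every stage.

## Worked example

```r
library(forestshift)

# a 60-town synthetic landscape with known ground truth
ls  <- simulate_landscape(sim_config(seed = 42))
cfg <- pipeline_config(outdir = file.path(tempdir(), "demo"), seed = 42,
                       n_sets = 25, n_rand = 2000, n_perm = 999,
                       class_width_km = 80)
res <- run_pipeline(ls$dataset, cfg)
print(res)
#> forestshift pipeline result
#>   towns analysed: 60
#>   mean change 0.349 (sd 0.103)
#>   beta diversity: pre 0.432, modern 0.420
#>   NMDS stress (k = 2): 0.1121

print(res$change)
#> Per-town compositional change (Sorensen): 60 towns
#>   regional mean 0.349 (sd 0.103), range [0.154, 0.568]
#>   ADIRON   n= 18  mean 0.306 (sd 0.093)
#>   APPAL    n= 12  mean 0.372 (sd 0.123)
#>   BROAD    n= 18  mean 0.391 (sd 0.097)
#>   LAUREN   n= 12  mean 0.326 (sd 0.081)

print(res$env_mantel)
#>     covariate         era         r_m     p
#> 1         gdd precolonial  0.91137582 0.001
#> 2         gdd      modern  0.85018878 0.001
#> 3   precip_mm precolonial  0.56716136 0.001
#> 4   precip_mm      modern  0.57475089 0.001
#> 5 elevation_m precolonial  0.06849244 0.082
#> 6 elevation_m      modern  0.06684931 0.073
#> 7    sand_pct precolonial -0.06116953 0.948
#> 8    sand_pct      modern -0.08200857 0.984

print(res$tree)
#> Conditional inference change tree: 1 split(s), 2 leaf/leaves, n = 60
#> [agri_peak <= 0.5599] p_adj = 0.0012, n = 60
#>   * leaf: mean = 0.2790, n = 34
#>   * leaf: mean = 0.4404, n = 26
```

Reading the output: every town passed the adequacy screen (the generator
samples generously by construction); the average town moved about a third
of the way to a disjoint composition; the modern era is slightly more
homogeneous than the pre-colonial one (beta 0.420 vs 0.432); composition
is strongly coupled to temperature in both eras but *less* so in the
modern era (r_M 0.85 vs 0.91) — the planted decoupling; and the regression
tree recovers peak agricultural clearing as the dominant driver of change,
splitting the towns at 56 % cleared.

`run_pipeline()` also writes per-stage CSV tables (change per town,
abundance-change table, correlograms, NMDS coordinates, tree report) and
a JSON manifest with the seed, parameters, and exclusion counts at every
filter stage to `cfg$outdir`.

Real data enter through `load_dataset(witness_csv, inventory_csv,
town_geojson, covariate_csv)`; the synthetic generator emits exactly those
formats (`write_landscape()`), so the on-disk interface is exercised by
the tests.

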