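Package: forestshift
Title: Compositional Change Between Witness-Tree Surveys and Modern Forest Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying four centuries of forest compositional change by
    comparing pre-colonial witness-tree records to modern forest-inventory plot data at
    the town scale. Provides record-level filtering and taxon binning, a bootstrap /
    Michaelis-Menten sampling-adequacy screen, abundance-based Sorensen dissimilarity and
    per-town change summaries, paired Monte Carlo and permutation tests, beta-diversity
    (biotic homogenization) comparisons, Moran's I and Mantel correlograms, NMDS
    ordination with environmental vector fitting, a permutation-based conditional
    inference regression tree for land-use drivers of change, and a synthetic-landscape
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
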