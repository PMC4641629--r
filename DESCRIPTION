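Package: reefhab
Title: Fuzzy Habitat Classification and Predictive Mapping of Biogenic Reef Assemblages
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies epibenthic assemblages of northern Adriatic biogenic
    reefs (tegnue) into fuzzy habitat types and predicts fuzzy habitat
    membership over a spatial grid from environmental predictors. Implements
    fuzzy k-means clustering of site-by-taxa tables, gridding of sparse
    oceanographic monitoring casts (seasonal and yearly medians, percentile
    ranges, moving-window in-filling), redundancy analysis of Hellinger
    transformed membership grades with permutation axis tests, forward
    selection with a double stopping criterion, variation partitioning over
    predictor groups, and projection of canonical coefficients onto gridded
    predictors to produce per-habitat membership rasters. A synthetic-data
    generator emulating the study design (stations on an onshore-offshore
    gradient, seasonal monitoring casts, current fields and bathymetry)
    provides a parameter-recovery test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
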