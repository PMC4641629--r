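#!/usr/bin/env Rscript
# Stage 6: habitat mapping -- the final RDA model's canonical coefficients
# applied to the gridded predictors, back-transformed to fuzzy membership
# rasters per habitat, with dominance and extrapolation masks and PNG
# quicklooks (white = low membership, dark = high).
library(reefhab)

dir.create("results/maps", showWarnings = FALSE, recursive = TRUE)

scenario <- synthetic_scenario(seed = 1)
st <- generate_stations(scenario)
community <- generate_community(st$truth, scenario)
casts <- generate_casts(st$stations, scenario)
hydro <- generate_current_layers(scenario)
spec <- scenario_grid(scenario)
layers <- build_predictor_layers(casts, spec)
pred <- site_predictor_table(layers, hydro, st$stations)
fit <- fkm_fit(hellinger_transform(community), k = 3, m = 2, n_init = 1000,
               seed = 101)
U <- align_clusters(fit, st$stations$expert_label)
Y <- hellinger_transform(U)
res <- two_step_subset_selection(Y, pred$groups, pred$depth,
                                 alpha = 0.05, n_perm = 999, seed = 202)

map <- predict_memberships(res$final, c(layers, hydro))
sm <- map_summary(map)

cat(sprintf("predicted %d of %d cells\n", sm$n_cells,
            spec$n_rows * spec$n_cols))
cat("dominant-habitat area fractions:",
    paste(names(sm$area_fraction),
          sprintf("%.2f", sm$area_fraction)), "\n")
cat(sprintf("cells flagged as extrapolation: %d\n",
            sum(map$extrapolation, na.rm = TRUE)))

write_habitat_map(map, "results/maps")
ramps <- list(FKM_A = "darkred", FKM_B = "darkblue", FKM_C = "darkgreen")
for (nm in names(map$memberships)) {
  png(file.path("results/maps", paste0("quicklook_", nm, ".png")),
      width = 640, height = 440)
  image(t(map$memberships[[nm]]),
        col = colorRampPalette(c("white", ramps[[nm]]))(64),
        axes = FALSE, main = paste("Predicted", nm, "membership"))
  dev.off()
}
cat("wrote membership/dominance/extrapolation rasters and quicklooks\n")
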