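#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- 33 stations on an onshore-offshore
# gradient, their ground-truth habitat memberships, the site-by-taxa community
# table, a year of monthly monitoring casts, and the gridded current and
# bathymetry fields.
library(reefhab)

dir.create("results/synthetic", showWarnings = FALSE, recursive = TRUE)

scenario <- synthetic_scenario(seed = 1)
print(scenario)
write_scenario(scenario, "results/synthetic/scenario.dcf")

st <- generate_stations(scenario)
community <- generate_community(st$truth, scenario)
casts <- generate_casts(st$stations, scenario)
hydro <- generate_current_layers(scenario)

cat(sprintf("stations: %d, depths %.1f-%.1f m, habitats %s\n",
            nrow(st$stations), min(st$stations$depth_m),
            max(st$stations$depth_m),
            paste(names(table(st$stations$expert_label)),
                  table(st$stations$expert_label), collapse = " ")))
cat(sprintf("community: %d taxa, %.0f%% zero cells\n", ncol(community),
            100 * mean(community == 0)))
cat(sprintf("casts: %d records over %d station-months\n", nrow(casts),
            length(unique(paste(casts$station_id, casts$date)))))

write.csv(st$stations, "results/synthetic/stations.csv", row.names = FALSE)
write.csv(data.frame(station_id = rownames(st$truth$memberships),
                     st$truth$memberships, check.names = FALSE),
          "results/synthetic/true_memberships.csv", row.names = FALSE)
write.csv(data.frame(site_id = rownames(community), community,
                     check.names = FALSE),
          "results/synthetic/community.csv", row.names = FALSE)
write.csv(casts, "results/synthetic/casts.csv", row.names = FALSE)
for (nm in names(hydro)) {
  write_esri_ascii(hydro[[nm]],
                   file.path("results/synthetic",
                             paste0(gsub("\\.", "_", nm), ".asc")))
}
cat("wrote station, truth, community, cast tables and hydro/bathymetry rasters\n")
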