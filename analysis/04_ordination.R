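#!/usr/bin/env Rscript
# Stage 4: direct gradient analysis -- RDA of the Hellinger-transformed
# membership grades on three predictor subsets (surface, bottom, hydro) with
# sequential axis permutation tests and forward selection (double stopping
# criterion), then the final model: union of selected variables plus depth.
library(reefhab)

dir.create("results/ordination", showWarnings = FALSE, recursive = TRUE)

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

for (g in names(res$selection)) {
  sel <- res$selection[[g]]
  cat(sprintf("%s subset (%d candidates): global adjR2 %.2f, selected: %s\n",
              g, ncol(pred$groups[[g]]), sel$global$adj_r2,
              if (length(sel$selected)) paste(sel$selected, collapse = ", ")
              else "(none)"))
}
fin <- res$final
cat(sprintf("final model: %d predictors, adjR2 = %.2f (axes: %s), p = %s\n",
            fin$p, fin$adj_r2,
            paste(sprintf("%.2f", fin$axis_adj_r2[1:2]), collapse = ", "),
            paste(format(fin$axis_p[1:2]), collapse = ", ")))
if (!is.null(res$reduced) && length(res$reduced$selection$selected)) {
  cat(sprintf("parsimonious alternative: %s (adjR2 = %.2f)\n",
              paste(res$reduced$selection$selected, collapse = ", "),
              res$reduced$model$adj_r2))
}

write.csv(data.frame(variable = fin$variables, fin$coefficients,
                     check.names = FALSE),
          "results/ordination/canonical_coefficients.csv", row.names = FALSE)
write.csv(data.frame(axis = paste0("RDA", seq_along(fin$eigenvalues)),
                     eigenvalue = fin$eigenvalues, axis_r2 = fin$axis_r2,
                     axis_adj_r2 = fin$axis_adj_r2,
                     p_value = fin$axis_p[seq_along(fin$eigenvalues)]),
          "results/ordination/final_model_axes.csv", row.names = FALSE)
write.csv(data.frame(fin$response_axis_fractions, check.names = FALSE),
          "results/ordination/response_axis_fractions.csv")
cat("wrote canonical coefficients, axis table and per-response fractions\n")
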