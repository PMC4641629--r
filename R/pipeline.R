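#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with the study-design
#' defaults: fuzziness m = 2, 1000 clustering restarts, 999 permutations,
#' alpha = 0.05, 2.5 km grid, 0.50 membership threshold. Validated on
#' construction; round-trips losslessly through [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param k number of habitat clusters.
#' @param m fuzziness exponent (> 1).
#' @param n_init clustering restarts.
#' @param n_perm permutations for all tests (>= 1).
#' @param alpha significance level in (0, 1).
#' @param threshold membership summary threshold in (0, 1).
#' @param tie_rule "strict" or "inclusive" threshold comparison.
#' @param renormalize renormalize predicted cell memberships to sum 1.
#' @param reduce run the second forward selection on the final model.
#' @param cluster_input "hellinger" (default) or "raw" community matrix fed
#'   to the clustering.
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 3, m = 2, n_init = 1000, n_perm = 999,
                            alpha = 0.05, threshold = 0.5,
                            tie_rule = "strict", renormalize = TRUE,
                            reduce = TRUE, cluster_input = "hellinger",
                            seed = 1L) {
  check <- function(ok, field, msg) {
    if (!ok) stop("invalid config field `", field, "`: ", msg)
  }
  check(is.numeric(k) && k >= 2, "k", "must be >= 2")
  check(is.numeric(m) && m > 1, "m", "must be > 1")
  check(is.numeric(n_init) && n_init >= 1, "n_init", "must be >= 1")
  check(is.numeric(n_perm) && n_perm >= 1, "n_perm", "must be >= 1")
  check(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha",
        "must lie in (0, 1)")
  check(is.numeric(threshold) && threshold > 0 && threshold < 1, "threshold",
        "must lie in (0, 1)")
  check(tie_rule %in% c("strict", "inclusive"), "tie_rule",
        "must be 'strict' or 'inclusive'")
  check(cluster_input %in% c("hellinger", "raw"), "cluster_input",
        "must be 'hellinger' or 'raw'")
  structure(
    list(k = as.integer(k), m = m, n_init = as.integer(n_init),
         n_perm = as.integer(n_perm), alpha = alpha, threshold = threshold,
         tie_rule = tie_rule, renormalize = isTRUE(renormalize),
         reduce = isTRUE(reduce), cluster_input = cluster_input,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  d <- as.data.frame(config[setdiff(names(config), character(0))])
  write.dcf(d, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  pipeline_config(
    k = as.numeric(d$k), m = as.numeric(d$m),
    n_init = as.numeric(d$n_init), n_perm = as.numeric(d$n_perm),
    alpha = as.numeric(d$alpha), threshold = as.numeric(d$threshold),
    tie_rule = d$tie_rule, renormalize = as.logical(d$renormalize),
    reduce = as.logical(d$reduce), cluster_input = d$cluster_input,
    seed = as.numeric(d$seed)
  )
}

#' Assemble the site-level predictor table from grid layers
#'
#' Extracts every layer at the station cells and groups the columns into the
#' subsets used by the two-step selection: surface and bottom water-quality
#' statistics, hydrodynamics, and depth.
#'
#' @param layers named list of [grid_layer()]s (cast-derived yearly layers).
#' @param hydro named list of hydrodynamic/bathymetry layers
#'   ([generate_current_layers()] names).
#' @param stations station data.frame with x_km, y_km.
#' @return list: `groups` (named list of matrices: surface, bottom, hydro),
#'   `depth` (1-column matrix), `all` (full matrix).
#' @export
site_predictor_table <- function(layers, hydro, stations) {
  pull <- function(ll) {
    out <- vapply(ll, function(l) extract_at_sites(l, stations),
                  numeric(nrow(stations)))
    colnames(out) <- names(ll)
    out
  }
  casts_mat <- pull(layers)
  side <- vapply(layers, function(l) l$layer, character(1))
  hydro_mat <- pull(hydro[c("Vmean.surface", "Vmax.surface",
                            "Vmean.bottom", "Vmax.bottom")])
  depth <- pull(hydro["Depth"])
  groups <- list(
    surface = casts_mat[, side == "surface", drop = FALSE],
    bottom = casts_mat[, side == "bottom", drop = FALSE],
    hydro = hydro_mat
  )
  list(groups = groups, depth = depth,
       all = cbind(casts_mat, hydro_mat, depth))
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes every stage in order -- simulate, grid, cluster, ordinate,
#' partition, predict, report -- and (optionally) writes the result tables
#' to a run directory. Identical scenario + config produce bit-identical
#' outputs.
#'
#' Stages: (1) generate stations, community, casts and hydrodynamic layers;
#' (2) grid the casts into yearly median and p95-p5 range layers with
#' moving-window in-filling; (3) fuzzy k-means on the (Hellinger-transformed)
#' community, aligned with the expert labels, with mismatch and threshold
#' summaries; (4) two-step subset forward selection and final RDA of the
#' Hellinger-transformed membership grades; (5) variation partitioning over
#' the parsimonious groups + depth; (6) projection of the final model onto
#' the grid; (7) validation against the scenario's ground truth.
#'
#' @param scenario a [synthetic_scenario()].
#' @param config a [pipeline_config()].
#' @param outdir optional run directory; when given, tables, model summaries,
#'   rasters and a log are written there.
#' @return list with elements `stations`, `truth`, `community`, `casts`,
#'   `layers`, `hydro`, `clustering` (fit, aligned memberships, mismatch,
#'   summary), `ordination` (two-step result), `partition`, `map`,
#'   `map_summary`, `validation` (membership MAE, per-cluster and pooled map
#'   correlation with truth), `config`.
#' @export
run_all <- function(scenario, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   sprintf(...))
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    say("stage %s: done", name)
    res
  }

  say("run_all: seed %d, k %d, m %g, n_init %d, n_perm %d",
      scenario$seed, config$k, config$m, config$n_init, config$n_perm)

  sim <- stage("simulate", {
    st <- generate_stations(scenario)
    comm <- generate_community(st$truth, scenario)
    casts <- generate_casts(st$stations, scenario)
    hydro <- generate_current_layers(scenario)
    list(st = st, comm = comm, casts = casts, hydro = hydro)
  })
  spec <- scenario_grid(scenario)

  layers <- stage("grid", build_predictor_layers(sim$casts, spec))

  clustering <- stage("cluster", {
    Xc <- if (config$cluster_input == "hellinger") {
      hellinger_transform(sim$comm)
    } else {
      sim$comm
    }
    fit <- fkm_fit(Xc, k = config$k, m = config$m, n_init = config$n_init,
                   seed = substream(scenario$seed, "cluster"))
    aligned <- align_clusters(fit, sim$st$stations$expert_label)
    list(fit = fit, memberships = aligned,
         mismatch = mismatch_report(aligned, sim$st$stations$expert_label),
         summary = membership_summary(aligned, threshold = config$threshold,
                                      tie_rule = config$tie_rule))
  })

  predictors <- stage("predictors",
                      site_predictor_table(layers, sim$hydro, sim$st$stations))

  ordination <- stage("ordinate", {
    Y <- hellinger_transform(clustering$memberships)
    two_step_subset_selection(Y, predictors$groups, predictors$depth,
                              alpha = config$alpha, n_perm = config$n_perm,
                              seed = substream(scenario$seed, "perm"),
                              reduce = config$reduce)
  })

  partition <- stage("partition", {
    Y <- hellinger_transform(clustering$memberships)
    groups <- list()
    for (g in names(predictors$groups)) {
      sel <- ordination$selection[[g]]$selected
      if (length(sel)) {
        groups[[tools::toTitleCase(g)]] <-
          predictors$groups[[g]][, sel, drop = FALSE]
      }
    }
    groups$Depth <- predictors$depth
    if (length(groups) >= 2) variation_partition(Y, groups) else NULL
  })

  map <- stage("predict", {
    all_layers <- c(layers, sim$hydro)
    predict_memberships(ordination$final, all_layers,
                        renormalize = config$renormalize)
  })
  msum <- map_summary(map)

  validation <- stage("validate", {
    truth_fields <- true_membership_fields(scenario, spec)
    mae <- mean(abs(clustering$memberships - sim$st$truth$memberships))
    cors <- vapply(names(map$memberships), function(nm) {
      pred <- as.numeric(map$memberships[[nm]])
      tr <- as.numeric(truth_fields[[nm]])
      ok <- !is.na(pred) & !is.na(tr)
      stats::cor(pred[ok], tr[ok])
    }, numeric(1))
    pooled <- {
      pred <- unlist(lapply(map$memberships, as.numeric))
      tr <- unlist(lapply(truth_fields[names(map$memberships)], as.numeric))
      ok <- !is.na(pred) & !is.na(tr)
      stats::cor(pred[ok], tr[ok])
    }
    list(membership_mae = mae, map_correlation = cors,
         pooled_map_correlation = pooled)
  })

  result <- list(stations = sim$st$stations, truth = sim$st$truth,
                 community = sim$comm, casts = sim$casts, layers = layers,
                 hydro = sim$hydro, clustering = clustering,
                 predictors = predictors, ordination = ordination,
                 partition = partition, map = map, map_summary = msum,
                 validation = validation, config = config, log = log_lines)

  if (!is.null(outdir)) write_run(result, outdir, scenario)
  result
}

# Write the standard result tables of a pipeline run.
write_run <- function(result, outdir, scenario) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(outdir, f),
                                          row.names = FALSE)
  wcsv(result$stations, "stations.csv")
  comm <- data.frame(site_id = rownames(result$community),
                     result$community, check.names = FALSE)
  wcsv(comm, "community.csv")
  wcsv(result$casts, "casts.csv")
  U <- result$clustering$memberships
  memb <- data.frame(station = rownames(U) %||% seq_len(nrow(U)),
                     typ = result$stations$expert_label,
                     round(unclass(U), 2), check.names = FALSE)
  wcsv(memb, "membership.csv")
  memb_full <- data.frame(station = memb$station, typ = memb$typ,
                          unclass(U), check.names = FALSE)
  wcsv(memb_full, "membership_full.csv")
  sm <- result$clustering$summary
  wcsv(data.frame(cluster = names(sm$counts), count_above = sm$counts,
                  min = sm$range["min", ], max = sm$range["max", ]),
       "membership_summary.csv")
  mm <- result$clustering$mismatch
  wcsv(data.frame(station = mm$mismatches), "mismatches.csv")
  fin <- result$ordination$final
  wcsv(data.frame(variable = fin$variables, fin$coefficients,
                  check.names = FALSE), "canonical_coefficients.csv")
  wcsv(data.frame(axis = paste0("RDA", seq_along(fin$eigenvalues)),
                  eigenvalue = fin$eigenvalues, axis_r2 = fin$axis_r2,
                  axis_adj_r2 = fin$axis_adj_r2,
                  p_value = if (is.null(fin$axis_p)) NA else
                    fin$axis_p[seq_along(fin$eigenvalues)]),
       "final_model_axes.csv")
  wcsv(data.frame(statistic = c("r2", "adj_r2"),
                  value = c(fin$r2, fin$adj_r2)), "final_model_fit.csv")
  if (!is.null(result$partition)) wcsv(result$partition, "partition.csv")
  write_habitat_map(result$map, file.path(outdir, "rasters"))
  wcsv(data.frame(
    metric = c("membership_mae",
               paste0("map_correlation_", names(result$validation$map_correlation)),
               "pooled_map_correlation"),
    value = c(result$validation$membership_mae,
              as.numeric(result$validation$map_correlation),
              result$validation$pooled_map_correlation)), "validation.csv")
  write_scenario(scenario, file.path(outdir, "scenario.dcf"))
  write_pipeline_config(result$config, file.path(outdir, "config.dcf"))
  writeLines(result$log, file.path(outdir, "log.txt"))
  invisible(outdir)
}
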