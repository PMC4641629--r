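#' Synthetic study scenario
#'
#' Parameters of the synthetic data generator that emulates the study design:
#' ~33 stations at 12.4-26 m depth along an onshore-offshore gradient, 3
#' latent habitat archetypes, monthly monitoring casts with occasional whole
#' seasons missing, nutrient/salinity gradients driven by distance from the
#' river mouth (latent axis 1) and a secondary coastal-variability axis
#' (latent axis 2), and a 2.5 x 2.5 km analysis grid.
#'
#' The latent structure is two-dimensional: axis 1 is the normalized
#' offshore distance (x / domain width; the freshwater source sits at x = 0)
#' and drives PHOS, nutrients, SAL and depth; axis 2 is a coastal-belt
#' secondary axis (y / domain height) and drives CPHL, its seasonal
#' variability, and the current fields. Habitat archetypes occupy fixed
#' positions on this latent plane and a station's true membership in habitat
#' h is its normalized inverse squared latent distance to archetype h.
#'
#' @param n_sites number of stations (default 33).
#' @param n_taxa number of (anonymous) taxa columns (default 40).
#' @param k_habitats number of habitat archetypes (default 3, >= 2).
#' @param domain_extent c(width, height) of the planar domain in km.
#' @param depth_range station depth range in m (default c(12.4, 26)).
#' @param archetype_positions k x 2 matrix of archetype positions on the
#'   latent plane (axis values in [0, 1]); default spreads k archetypes along
#'   axis 1.
#' @param archetype_profiles k x n_taxa nonnegative expected-abundance
#'   matrix; default gives each archetype a distinct smooth peak over the
#'   taxa axis on a low common baseline.
#' @param abundance_scale multiplier on expected abundances (the field data
#'   scale -- percent cover vs counts -- is not fixed by the design).
#' @param noise_sd standard deviation of the lognormal (multiplicative)
#'   abundance noise on the log scale (default 0.2, "low noise").
#' @param env_noise_sd multiplier on the per-variable cast noise SDs.
#' @param missing_season_rate probability that a station misses a whole
#'   season of casts (default 0.1).
#' @param detection_floor abundances below this value are recorded as 0.
#' @param cell_size analysis grid cell edge (km, default 2.5).
#' @param seed global seed; expanded into per-component substreams.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_sites = 33, n_taxa = 40, k_habitats = 3,
                               domain_extent = c(60, 40),
                               depth_range = c(12.4, 26),
                               archetype_positions = NULL,
                               archetype_profiles = NULL,
                               abundance_scale = 1,
                               noise_sd = 0.2,
                               env_noise_sd = 1,
                               missing_season_rate = 0.1,
                               detection_floor = 0.01,
                               cell_size = 2.5,
                               seed = 1L) {
  if (n_sites < 1) stop("invalid scenario: n_sites must be positive")
  if (k_habitats < 2) stop("invalid scenario: k_habitats must be >= 2")
  if (noise_sd < 0) stop("invalid scenario: noise_sd must be >= 0")
  if (missing_season_rate < 0 || missing_season_rate > 1) {
    stop("invalid scenario: missing_season_rate must lie in [0, 1]")
  }
  k <- as.integer(k_habitats)
  if (is.null(archetype_positions)) {
    ax1 <- seq(0.12, 0.88, length.out = k)
    ax2 <- rep(c(0.7, 0.3), length.out = k)
    archetype_positions <- cbind(ax1, ax2)
  }
  archetype_positions <- as.matrix(archetype_positions)
  stopifnot(nrow(archetype_positions) == k, ncol(archetype_positions) == 2)
  if (is.null(archetype_profiles)) {
    centers <- (seq_len(k) - 0.5) * n_taxa / k
    width <- n_taxa / (3 * k)
    j <- seq_len(n_taxa)
    archetype_profiles <- t(vapply(centers, function(cc) {
      0.2 + 10 * exp(-0.5 * ((j - cc) / width)^2)
    }, numeric(n_taxa)))
  }
  archetype_profiles <- as.matrix(archetype_profiles) * abundance_scale
  stopifnot(nrow(archetype_profiles) == k, ncol(archetype_profiles) == n_taxa)
  if (any(archetype_profiles < 0)) {
    stop("invalid scenario: expected abundances must be >= 0")
  }
  d <- as.matrix(stats::dist(archetype_profiles))
  if (any(d[upper.tri(d)] == 0)) {
    stop("invalid scenario: archetype profiles must be pairwise distinct")
  }
  structure(
    list(n_sites = as.integer(n_sites), n_taxa = as.integer(n_taxa),
         k_habitats = k, domain_extent = as.numeric(domain_extent),
         depth_range = as.numeric(depth_range),
         archetype_positions = archetype_positions,
         archetype_profiles = archetype_profiles,
         gradient_loadings = default_gradient_loadings(),
         abundance_scale = abundance_scale,
         noise_sd = noise_sd, env_noise_sd = env_noise_sd,
         missing_season_rate = missing_season_rate,
         detection_floor = detection_floor,
         cell_size = cell_size, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scenario: %d sites, %d taxa, %d habitats, ",
                     "%g x %g km domain, noise_sd %g, seed %d\n"),
              x$n_sites, x$n_taxa, x$k_habitats, x$domain_extent[1],
              x$domain_extent[2], x$noise_sd, x$seed))
  invisible(x)
}

# Linear loadings of the two latent axes on each monitored variable:
# value(depth layer) = intercept + slope_ax1 * ax1 + slope_ax2 * ax2, with a
# seasonal sine of amplitude seas_amp * (1 + amp_slope_ax2 * ax2) and Gaussian
# cast noise noise_sd. Magnitudes are typical for the northern Adriatic
# coastal zone.
default_gradient_loadings <- function() {
  rbind(
    data.frame(variable = "TEMP", layer = "surface", intercept = 16.0,
               slope_ax1 = -0.5, slope_ax2 = 0.5, seas_amp = 7.0,
               amp_slope_ax2 = 0, noise_sd = 0.5),
    data.frame(variable = "TEMP", layer = "bottom", intercept = 14.5,
               slope_ax1 = -1.5, slope_ax2 = 0.3, seas_amp = 5.0,
               amp_slope_ax2 = 0, noise_sd = 0.5),
    data.frame(variable = "SAL", layer = "surface", intercept = 33.0,
               slope_ax1 = 4.0, slope_ax2 = -0.8, seas_amp = 0.6,
               amp_slope_ax2 = 0, noise_sd = 0.25),
    data.frame(variable = "SAL", layer = "bottom", intercept = 35.5,
               slope_ax1 = 2.0, slope_ax2 = -0.4, seas_amp = 0.3,
               amp_slope_ax2 = 0, noise_sd = 0.2),
    data.frame(variable = "DOX", layer = "surface", intercept = 5.8,
               slope_ax1 = -0.4, slope_ax2 = 0.2, seas_amp = 0.5,
               amp_slope_ax2 = 0, noise_sd = 0.15),
    data.frame(variable = "DOX", layer = "bottom", intercept = 5.2,
               slope_ax1 = -0.8, slope_ax2 = 0.1, seas_amp = 0.6,
               amp_slope_ax2 = 0, noise_sd = 0.15),
    data.frame(variable = "AMON", layer = "surface", intercept = 2.8,
               slope_ax1 = -2.0, slope_ax2 = 0.3, seas_amp = 0.4,
               amp_slope_ax2 = 0, noise_sd = 0.15),
    data.frame(variable = "AMON", layer = "bottom", intercept = 2.2,
               slope_ax1 = -1.4, slope_ax2 = 0.2, seas_amp = 0.3,
               amp_slope_ax2 = 0, noise_sd = 0.12),
    data.frame(variable = "NTRA", layer = "surface", intercept = 18.0,
               slope_ax1 = -14.0, slope_ax2 = 1.5, seas_amp = 2.5,
               amp_slope_ax2 = 0, noise_sd = 0.8),
    data.frame(variable = "NTRA", layer = "bottom", intercept = 12.0,
               slope_ax1 = -8.0, slope_ax2 = 1.0, seas_amp = 1.5,
               amp_slope_ax2 = 0, noise_sd = 0.6),
    data.frame(variable = "PHOS", layer = "surface", intercept = 1.5,
               slope_ax1 = -1.2, slope_ax2 = 0.15, seas_amp = 0.12,
               amp_slope_ax2 = 0, noise_sd = 0.04),
    data.frame(variable = "PHOS", layer = "bottom", intercept = 1.2,
               slope_ax1 = -0.9, slope_ax2 = 0.1, seas_amp = 0.1,
               amp_slope_ax2 = 0.8, noise_sd = 0.04),
    data.frame(variable = "CPHL", layer = "surface", intercept = 2.6,
               slope_ax1 = -1.6, slope_ax2 = 1.2, seas_amp = 0.8,
               amp_slope_ax2 = 1.5, noise_sd = 0.15),
    data.frame(variable = "CPHL", layer = "bottom", intercept = 1.8,
               slope_ax1 = -1.0, slope_ax2 = 0.8, seas_amp = 0.5,
               amp_slope_ax2 = 1.0, noise_sd = 0.12)
  )
}

# Latent axis values of planar coordinates.
latent_axes <- function(scenario, x_km, y_km) {
  cbind(ax1 = x_km / scenario$domain_extent[1],
        ax2 = y_km / scenario$domain_extent[2])
}

# True membership of latent positions: normalized inverse squared distance to
# the archetype positions; a position coinciding with an archetype is crisp.
true_membership_at <- function(scenario, ax) {
  A <- scenario$archetype_positions
  k <- nrow(A)
  U <- matrix(0, nrow(ax), k)
  for (i in seq_len(nrow(ax))) {
    d2 <- colSums((t(A) - ax[i, ])^2)
    if (any(d2 == 0)) {
      U[i, d2 == 0] <- 1 / sum(d2 == 0)
    } else {
      w <- 1 / d2
      U[i, ] <- w / sum(w)
    }
  }
  colnames(U) <- paste0("FKM_", LETTERS[seq_len(k)])
  U
}

# Noise-free value of a monitored variable at a planar position.
env_field_value <- function(scenario, variable, layer, x_km, y_km) {
  gl <- scenario$gradient_loadings
  row <- gl[gl$variable == variable & gl$layer == layer, ]
  if (nrow(row) != 1) stop("no gradient loading for ", variable, "/", layer)
  ax <- latent_axes(scenario, x_km, y_km)
  row$intercept + row$slope_ax1 * ax[, "ax1"] + row$slope_ax2 * ax[, "ax2"]
}

#' Grid specification implied by a scenario
#'
#' @param scenario a [synthetic_scenario()].
#' @return [grid_spec()] covering the scenario's domain.
#' @export
scenario_grid <- function(scenario) {
  grid_spec(origin = c(0, 0), cell_size = scenario$cell_size,
            n_rows = ceiling(scenario$domain_extent[2] / scenario$cell_size),
            n_cols = ceiling(scenario$domain_extent[1] / scenario$cell_size))
}

#' Generate stations and their true habitat memberships
#'
#' Stations are stratified along the onshore-offshore axis (so the gradient
#' is covered) with uniform alongshore positions; depth increases offshore
#' over `depth_range` with station-level jitter. True memberships are the
#' normalized inverse squared latent distances to the archetypes; the expert
#' label of a station is its highest-membership archetype.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list: `stations` (data.frame station_id, x_km, y_km, depth_m,
#'   expert_label), `truth` (list with `memberships`, `latent`,
#'   `archetype_positions`).
#' @export
generate_stations <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_sites
  w <- scenario$domain_extent[1]; h <- scenario$domain_extent[2]
  with_seed(substream(scenario$seed, "stations"), {
    x <- ((seq_len(n) - 0.5) / n + stats::runif(n, -0.4, 0.4) / n) * w
    x <- pmin(pmax(x, 0.01 * w), 0.99 * w)
    y <- stats::runif(n, 0.05 * h, 0.95 * h)
    ax <- latent_axes(scenario, x, y)
    dr <- scenario$depth_range
    depth <- dr[1] + (dr[2] - dr[1]) * ax[, "ax1"] + stats::rnorm(n, 0, 0.6)
    depth <- pmin(pmax(depth, dr[1]), dr[2])
    U <- true_membership_at(scenario, ax)
    labels <- LETTERS[apply(U, 1, which.max)]
    ids <- sprintf("ST%02d", seq_len(n))
    rownames(U) <- ids
    list(
      stations = data.frame(station_id = ids, x_km = x, y_km = y,
                            depth_m = depth, expert_label = labels,
                            stringsAsFactors = FALSE),
      truth = list(memberships = U, latent = ax,
                   archetype_positions = scenario$archetype_positions)
    )
  })
}

#' Generate a site-by-taxa community matrix
#'
#' The expected abundance of taxon j at site i is the membership-weighted
#' mixture of the archetype profiles, `sum_h u_ih * profile[h, j]`; observed
#' abundances multiply the expectation by lognormal noise
#' `exp(N(0, noise_sd))` and values below the detection floor are recorded
#' as 0. With `noise_sd = 0` a crisp site reproduces its archetype profile
#' exactly and a fuzzy site the exact convex combination.
#'
#' @param truth the `truth` element of [generate_stations()].
#' @param scenario a [synthetic_scenario()].
#' @return numeric matrix sites x taxa with station ids as rownames.
#' @export
generate_community <- function(truth, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  U <- truth$memberships
  if (ncol(U) != scenario$k_habitats || nrow(U) != scenario$n_sites) {
    stop("truth and scenario dimensions disagree")
  }
  expected <- U %*% scenario$archetype_profiles
  with_seed(substream(scenario$seed, "community"), {
    noise <- if (scenario$noise_sd > 0) {
      matrix(exp(stats::rnorm(length(expected), 0, scenario$noise_sd)),
             nrow(expected), ncol(expected))
    } else {
      1
    }
    obs <- expected * noise
    obs[obs < scenario$detection_floor] <- 0
    colnames(obs) <- sprintf("taxon_%02d", seq_len(ncol(obs)))
    rownames(obs) <- rownames(U)
    obs
  })
}

#' Generate monthly monitoring casts
#'
#' For each station and month, one vertical cast with records at the surface
#' (0.5 m), mid-depth and the local bottom depth. A record's value is the
#' noise-free field value at the station (interpolated linearly between the
#' surface and bottom fields over record depth) plus a deterministic seasonal
#' sine term and Gaussian noise. Whole seasons are dropped per station with
#' probability `missing_season_rate`.
#'
#' @param stations the `stations` element of [generate_stations()].
#' @param scenario a [synthetic_scenario()].
#' @param year calendar year stamped on the records (default 2019).
#' @return long data.frame: station_id, x_km, y_km, date, depth_m, then one
#'   column per variable acronym.
#' @export
generate_casts <- function(stations, scenario, year = 2019) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  gl <- scenario$gradient_loadings
  vars <- unique(gl$variable)
  with_seed(substream(scenario$seed, "casts"), {
    rows <- list()
    for (i in seq_len(nrow(stations))) {
      st <- stations[i, ]
      ax <- latent_axes(scenario, st$x_km, st$y_km)
      season_of_month <- (seq_len(12) - 1L) %/% 3L + 1L
      dropped <- stats::runif(4) < scenario$missing_season_rate
      depths <- c(0.5, st$depth_m / 2, st$depth_m)
      for (mo in seq_len(12)) {
        if (dropped[season_of_month[mo]]) next
        date <- as.Date(sprintf("%d-%02d-15", year, mo))
        vals <- matrix(NA_real_, length(depths), length(vars))
        colnames(vals) <- vars
        for (v in vars) {
          rs <- gl[gl$variable == v & gl$layer == "surface", ]
          rb <- gl[gl$variable == v & gl$layer == "bottom", ]
          v_surf <- rs$intercept + rs$slope_ax1 * ax[, "ax1"] +
            rs$slope_ax2 * ax[, "ax2"]
          v_bot <- rb$intercept + rb$slope_ax1 * ax[, "ax1"] +
            rb$slope_ax2 * ax[, "ax2"]
          frac <- depths / st$depth_m
          base <- v_surf + (v_bot - v_surf) * frac
          amp <- (rs$seas_amp * (1 + rs$amp_slope_ax2 * ax[, "ax2"])) *
            (1 - frac) +
            (rb$seas_amp * (1 + rb$amp_slope_ax2 * ax[, "ax2"])) * frac
          seas <- amp * sin(2 * pi * (mo - 4.5) / 12)
          nsd <- (rs$noise_sd * (1 - frac) + rb$noise_sd * frac) *
            scenario$env_noise_sd
          vals[, v] <- base + seas +
            if (any(nsd > 0)) stats::rnorm(length(depths), 0, nsd) else 0
        }
        rows[[length(rows) + 1L]] <- data.frame(
          station_id = st$station_id, x_km = st$x_km, y_km = st$y_km,
          date = date, depth_m = depths, vals,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) {
      out <- data.frame(station_id = character(0), x_km = numeric(0),
                        y_km = numeric(0), date = as.Date(character(0)),
                        depth_m = numeric(0))
      for (v in vars) out[[v]] <- numeric(0)
      return(out)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Low-order smooth random field on [0,1]^2, mean 0, O(1) amplitude.
smooth_field <- function(ax, n_modes = 3) {
  val <- numeric(nrow(ax))
  for (m in seq_len(n_modes)) {
    a <- stats::rnorm(4, 0, 1 / m)
    val <- val + a[1] * sin(pi * m * ax[, 1]) + a[2] * cos(pi * m * ax[, 1]) +
      a[3] * sin(pi * m * ax[, 2]) + a[4] * cos(pi * m * ax[, 2])
  }
  val / n_modes
}

#' Generate current-speed and bathymetry grid layers
#'
#' Mean and maximum current speeds (surface and bottom) as smooth random
#' fields with an onshore intensification (stronger coastal currents), and a
#' bathymetry layer deepening offshore. These stand in for pre-gridded
#' hydrodynamic model outputs and are consumed as-is by the pipeline (no
#' cast processing).
#'
#' @param scenario a [synthetic_scenario()].
#' @param spec optional [grid_spec()] (default [scenario_grid()]).
#' @return named list of [grid_layer()]s: `Vmean.surface`, `Vmax.surface`,
#'   `Vmean.bottom`, `Vmax.bottom`, `Depth`.
#' @export
generate_current_layers <- function(scenario, spec = scenario_grid(scenario)) {
  centers <- grid_cell_centers(spec)
  ax <- latent_axes(scenario, centers$x_km, centers$y_km)
  with_seed(substream(scenario$seed, "fields"), {
    to_mat <- function(v) {
      m <- matrix(NA_real_, spec$n_rows, spec$n_cols)
      m[cbind(centers$row, centers$col)] <- v
      m
    }
    vmean_s <- pmax(0.02, 0.28 - 0.15 * ax[, "ax1"] + 0.06 * ax[, "ax2"] +
                      0.04 * smooth_field(ax))
    vmax_s <- vmean_s * (2.2 + 0.3 * pmax(0, smooth_field(ax)))
    vmean_b <- pmax(0.01, 0.45 * vmean_s + 0.02 * smooth_field(ax))
    vmax_b <- vmean_b * (2.0 + 0.2 * pmax(0, smooth_field(ax)))
    dr <- scenario$depth_range
    depth <- dr[1] + (dr[2] - dr[1]) * ax[, "ax1"] + 0.5 * smooth_field(ax)
    mk <- function(v, nm) grid_layer(spec, to_mat(v), variable = nm,
                                     statistic = "median", layer = "static",
                                     period = "yearly")
    list(
      Vmean.surface = mk(vmean_s, "Vmean.surface"),
      Vmax.surface = mk(vmax_s, "Vmax.surface"),
      Vmean.bottom = mk(vmean_b, "Vmean.bottom"),
      Vmax.bottom = mk(vmax_b, "Vmax.bottom"),
      Depth = mk(depth, "Depth")
    )
  })
}

#' Noise-free true membership fields on the analysis grid
#'
#' Ground truth for validating predicted habitat maps: the true membership of
#' every cell center, by the same latent-axis rule used for the stations.
#'
#' @param scenario a [synthetic_scenario()].
#' @param spec optional [grid_spec()].
#' @return list of k matrices (one per habitat), names `FKM_A`, `FKM_B`, ...
#' @export
true_membership_fields <- function(scenario, spec = scenario_grid(scenario)) {
  centers <- grid_cell_centers(spec)
  ax <- latent_axes(scenario, centers$x_km, centers$y_km)
  U <- true_membership_at(scenario, ax)
  out <- lapply(seq_len(ncol(U)), function(h) {
    m <- matrix(NA_real_, spec$n_rows, spec$n_cols)
    m[cbind(centers$row, centers$col)] <- U[, h]
    m
  })
  stats::setNames(out, colnames(U))
}

#' Write a scenario to a key-value config file
#'
#' Scalar fields are serialized as `key: value` lines (DCF); matrix-valued
#' fields (archetype positions/profiles, gradient loadings) are regenerated
#' from the scalars on read, so a default-derived scenario round-trips
#' losslessly.
#'
#' @param scenario a [synthetic_scenario()].
#' @param path output file.
#' @export
write_scenario <- function(scenario, path) {
  fields <- data.frame(
    n_sites = scenario$n_sites, n_taxa = scenario$n_taxa,
    k_habitats = scenario$k_habitats,
    domain_width = scenario$domain_extent[1],
    domain_height = scenario$domain_extent[2],
    depth_min = scenario$depth_range[1], depth_max = scenario$depth_range[2],
    abundance_scale = scenario$abundance_scale,
    noise_sd = scenario$noise_sd, env_noise_sd = scenario$env_noise_sd,
    missing_season_rate = scenario$missing_season_rate,
    detection_floor = scenario$detection_floor,
    cell_size = scenario$cell_size, seed = scenario$seed
  )
  write.dcf(fields, path)
  invisible(path)
}

#' Read a scenario from a key-value config file
#'
#' @param path file written by [write_scenario()].
#' @return a [synthetic_scenario()].
#' @export
read_scenario <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  num <- function(k) as.numeric(d[[k]])
  synthetic_scenario(
    n_sites = num("n_sites"), n_taxa = num("n_taxa"),
    k_habitats = num("k_habitats"),
    domain_extent = c(num("domain_width"), num("domain_height")),
    depth_range = c(num("depth_min"), num("depth_max")),
    abundance_scale = num("abundance_scale"),
    noise_sd = num("noise_sd"), env_noise_sd = num("env_noise_sd"),
    missing_season_rate = num("missing_season_rate"),
    detection_floor = num("detection_floor"),
    cell_size = num("cell_size"), seed = num("seed")
  )
}
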