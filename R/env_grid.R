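#' Water-column variables handled by the gridding stage
#'
#' Acronyms, units and moving-window defaults for the monitoring variables:
#' TEMP (deg C), SAL (unitless), DOX (mL/L), AMON/NTRA/PHOS (umol/L),
#' CPHL (ug/L). TEMP, SAL and CPHL use a 20 km search radius with at least 10
#' points; the other variables use 30 km and at least 6 points.
#'
#' @return data.frame with columns variable, unit, radius_km, min_points.
#' @export
env_variables <- function() {
  data.frame(
    variable = c("TEMP", "SAL", "DOX", "AMON", "NTRA", "PHOS", "CPHL"),
    unit = c("degC", "", "mL/L", "umol/L", "umol/L", "umol/L", "ug/L"),
    radius_km = c(20, 20, 30, 30, 30, 30, 20),
    min_points = c(10L, 10L, 6L, 6L, 6L, 6L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Assign a calendar date to an oceanographic season
#'
#' Seasons follow the monitoring convention: winter = Jan-Mar, spring =
#' Apr-Jun, summer = Jul-Sep, autumn = Oct-Dec.
#'
#' @param dates Date vector (or anything `as.Date()` accepts).
#' @return factor with levels winter, spring, summer, autumn.
#' @export
assign_season <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  lev <- c("winter", "spring", "summer", "autumn")
  factor(lev[(m - 1L) %/% 3L + 1L], levels = lev)
}

#' Surface and bottom records of a single cast
#'
#' From the records of one vertical cast (one station, one date), the surface
#' value is the shallowest record and the bottom value the deepest record,
#' subject to a minimum bottom depth of 5 m: if no record reaches 5 m the cast
#' yields no bottom value (very shallow casts would otherwise duplicate the
#' surface signal at the "bottom").
#'
#' @param cast data.frame with a `depth_m` column (other columns carried
#'   through), the records of one station/date.
#' @param min_bottom_depth minimum depth for a record to qualify as bottom (m).
#' @return list with elements `surface` and `bottom`, each a one-row
#'   data.frame or NULL (both NULL for an empty cast).
#' @export
extract_surface_bottom <- function(cast, min_bottom_depth = 5) {
  if (is.null(cast) || nrow(cast) == 0) {
    return(list(surface = NULL, bottom = NULL))
  }
  stopifnot("depth_m" %in% names(cast))
  if (any(cast$depth_m < 0)) stop("negative record depth")
  surface <- cast[which.min(cast$depth_m), , drop = FALSE]
  deep <- cast[cast$depth_m >= min_bottom_depth, , drop = FALSE]
  bottom <- if (nrow(deep) > 0) deep[which.max(deep$depth_m), , drop = FALSE] else NULL
  list(surface = surface, bottom = bottom)
}

#' Split cast records into per-cast surface and bottom tables
#'
#' Applies [extract_surface_bottom()] to every (station, date) group of a long
#' cast-record table.
#'
#' @param records data.frame with columns station_id, x_km, y_km, date,
#'   depth_m and one column per variable acronym.
#' @param min_bottom_depth passed to [extract_surface_bottom()].
#' @return list with data.frames `surface` and `bottom` (one row per cast).
#' @export
surface_bottom_records <- function(records, min_bottom_depth = 5) {
  key <- interaction(records$station_id, records$date, drop = TRUE)
  pieces <- split(records, key)
  surf <- list(); bot <- list()
  for (nm in names(pieces)) {
    sb <- extract_surface_bottom(pieces[[nm]], min_bottom_depth)
    surf[[nm]] <- sb$surface
    if (!is.null(sb$bottom)) bot[[nm]] <- sb$bottom
  }
  list(
    surface = do.call(rbind, c(surf, list(make.row.names = FALSE))),
    bottom = if (length(bot)) do.call(rbind, c(bot, list(make.row.names = FALSE))) else NULL
  )
}

# Per-cell grouping of point records: returns integer cell id (row-major) or NA.
cell_of <- function(spec, x, y) {
  idx <- grid_cell_index(spec, x, y)
  ifelse(is.na(idx$row), NA_integer_, (idx$row - 1L) * spec$n_cols + idx$col)
}

#' Seasonal and yearly median grid layers
#'
#' Computes, for one variable, the per-cell median of all values falling in
#' the cell for each season, and a yearly layer defined as the median of the
#' four seasonal medians -- present only where all four seasons have data.
#' Computing seasonal medians first prevents seasons with denser sampling from
#' dominating the yearly statistic.
#'
#' @param records data.frame with columns x_km, y_km, date and the variable
#'   column named by `variable`.
#' @param spec a [grid_spec()].
#' @param variable acronym naming the value column in `records`.
#' @param layer "surface" or "bottom" (metadata tag only).
#' @return named list of [grid_layer()]s: winter, spring, summer, autumn,
#'   yearly.
#' @export
seasonal_and_yearly_medians <- function(records, spec, variable,
                                        layer = "surface") {
  stopifnot(variable %in% names(records))
  vals <- records[[variable]]
  keep <- !is.na(vals)
  records <- records[keep, , drop = FALSE]
  vals <- vals[keep]
  season <- assign_season(records$date)
  cell <- cell_of(spec, records$x_km, records$y_km)
  in_grid <- !is.na(cell)
  seasons <- c("winter", "spring", "summer", "autumn")
  out <- list()
  seas_mats <- array(NA_real_, c(spec$n_rows, spec$n_cols, 4L))
  for (si in seq_along(seasons)) {
    sel <- in_grid & season == seasons[si]
    m <- matrix(NA_real_, spec$n_rows, spec$n_cols)
    if (any(sel)) {
      med <- tapply(vals[sel], cell[sel], stats::median)
      ids <- as.integer(names(med))
      m[cbind((ids - 1L) %/% spec$n_cols + 1L,
              (ids - 1L) %% spec$n_cols + 1L)] <- as.numeric(med)
    }
    seas_mats[, , si] <- m
    out[[seasons[si]]] <- grid_layer(spec, m, variable = variable,
                                     statistic = "median", layer = layer,
                                     period = seasons[si])
  }
  yearly <- apply(seas_mats, c(1, 2), function(v) {
    if (any(is.na(v))) NA_real_ else stats::median(v)
  })
  out$yearly <- grid_layer(spec, yearly, variable = variable,
                           statistic = "median", layer = layer,
                           period = "yearly")
  out
}

#' Yearly percentile-range grid layer
#'
#' Per-cell range of variation between the 95th and 5th percentiles of all
#' records pooled over the year, gated by the same all-four-seasons presence
#' rule as the yearly medians. Percentiles beat min/max because occasional
#' extreme records would otherwise bias the ranges; they are computed with
#' linear interpolation between closest order statistics
#' (`stats::quantile(type = 7)`).
#'
#' @inheritParams seasonal_and_yearly_medians
#' @param require_all_seasons gate cells on records from all four seasons
#'   (default TRUE); disable for data without seasonal structure.
#' @return a [grid_layer()] with statistic "range", period "yearly".
#' @export
percentile_range <- function(records, spec, variable, layer = "surface",
                             require_all_seasons = TRUE) {
  stopifnot(variable %in% names(records))
  vals <- records[[variable]]
  keep <- !is.na(vals)
  records <- records[keep, , drop = FALSE]
  vals <- vals[keep]
  season <- assign_season(records$date)
  cell <- cell_of(spec, records$x_km, records$y_km)
  ok <- !is.na(cell)
  m <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  if (any(ok)) {
    by_cell <- split(seq_len(nrow(records))[ok], cell[ok])
    for (id_chr in names(by_cell)) {
      rows <- by_cell[[id_chr]]
      if (require_all_seasons && length(unique(season[rows])) < 4L) next
      q <- stats::quantile(vals[rows], c(0.05, 0.95), type = 7, names = FALSE)
      id <- as.integer(id_chr)
      m[(id - 1L) %/% spec$n_cols + 1L, (id - 1L) %% spec$n_cols + 1L] <-
        q[2] - q[1]
    }
  }
  grid_layer(spec, m, variable = variable, statistic = "range",
             layer = layer, period = "yearly")
}

#' Moving-window in-filling of a sparse grid layer
#'
#' Missing cells are filled with the median of all raw data points lying in
#' cells whose centers are within `radius_km` of the target cell center,
#' provided at least `min_points` such points exist. Populated cells are never
#' modified, and filling draws on the original point data only (no cascade
#' from previously filled cells), which makes the operation idempotent.
#'
#' @param layer a [grid_layer()] with missing cells.
#' @param records data.frame of the raw points behind the layer (columns
#'   x_km, y_km and the layer's variable); for range layers pass the per-cell
#'   statistic as points via `values`/`points_xy` instead.
#' @param radius_km search radius (km) between cell centers.
#' @param min_points minimum number of points required to fill a cell.
#' @param values optional numeric vector of point values, overriding
#'   `records[[layer$variable]]`.
#' @return the filled [grid_layer()].
#' @export
moving_window_fill <- function(layer, records, radius_km, min_points,
                               values = NULL) {
  stopifnot(inherits(layer, "grid_layer"))
  if (!is.numeric(radius_km) || radius_km <= 0) stop("radius_km must be > 0")
  if (min_points < 1) stop("min_points must be >= 1")
  spec <- layer$spec
  vals <- values %||% records[[layer$variable]]
  if (is.null(vals)) stop("no point values found for variable ", layer$variable)
  keep <- !is.na(vals)
  px <- records$x_km[keep]; py <- records$y_km[keep]; pv <- vals[keep]
  idx <- grid_cell_index(spec, px, py)
  ok <- !is.na(idx$row)
  px <- px[ok]; py <- py[ok]; pv <- pv[ok]
  # points are attributed to their containing cell's center for the distance
  # test: "points within the surrounding cells" in a given radius
  pcx <- spec$origin[1] + (idx$col[ok] - 0.5) * spec$cell_size
  pcy <- spec$origin[2] + (idx$row[ok] - 0.5) * spec$cell_size
  out <- layer$values
  missing_cells <- which(is.na(out), arr.ind = TRUE)
  if (nrow(missing_cells) == 0 || length(pv) == 0) return(layer)
  tcx <- spec$origin[1] + (missing_cells[, "col"] - 0.5) * spec$cell_size
  tcy <- spec$origin[2] + (missing_cells[, "row"] - 0.5) * spec$cell_size
  r2 <- radius_km^2
  for (i in seq_len(nrow(missing_cells))) {
    d2 <- (pcx - tcx[i])^2 + (pcy - tcy[i])^2
    sel <- d2 <= r2
    if (sum(sel) >= min_points) {
      out[missing_cells[i, "row"], missing_cells[i, "col"]] <-
        stats::median(pv[sel])
    }
  }
  grid_layer(spec, out, variable = layer$variable, statistic = layer$statistic,
             layer = layer$layer, period = layer$period)
}

#' Build the full predictor layer set from cast records
#'
#' Runs the complete gridding chain for every monitoring variable: splits
#' casts into surface/bottom records, computes yearly medians and p95-p5
#' ranges per cell, and fills gaps with the per-variable moving-window
#' defaults of [env_variables()]. Pre-gridded hydrodynamic and bathymetry
#' layers are passed through untouched.
#'
#' @param records long cast-record table (see [surface_bottom_records()]).
#' @param spec a [grid_spec()].
#' @param variables acronyms to process (default all of [env_variables()]).
#' @param fill apply moving-window in-filling (default TRUE).
#' @return named list of yearly [grid_layer()]s, keys like
#'   `"PHOS.median.surface.yearly"`.
#' @export
build_predictor_layers <- function(records, spec,
                                   variables = env_variables()$variable,
                                   fill = TRUE) {
  sb <- surface_bottom_records(records)
  defaults <- env_variables()
  out <- list()
  for (v in variables) {
    par <- defaults[defaults$variable == v, ]
    radius <- if (nrow(par)) par$radius_km else 30
    minp <- if (nrow(par)) par$min_points else 6L
    for (side in c("surface", "bottom")) {
      recs <- sb[[side]]
      if (is.null(recs)) next
      med <- seasonal_and_yearly_medians(recs, spec, v, layer = side)$yearly
      rng <- percentile_range(recs, spec, v, layer = side)
      if (fill) {
        med <- moving_window_fill(med, recs, radius, minp)
        # ranges are a per-cell statistic, so the same window/threshold is
        # applied to the populated cell values rather than raw casts
        filled_cells <- which(!is.na(rng$values), arr.ind = TRUE)
        if (nrow(filled_cells) > 0) {
          centers <- data.frame(
            x_km = spec$origin[1] + (filled_cells[, "col"] - 0.5) * spec$cell_size,
            y_km = spec$origin[2] + (filled_cells[, "row"] - 0.5) * spec$cell_size
          )
          rng <- moving_window_fill(rng, centers, radius, min_points = 1L,
                                    values = rng$values[filled_cells])
        }
      }
      out[[layer_id(med)]] <- med
      out[[layer_id(rng)]] <- rng
    }
  }
  out
}
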