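#' Analysis grid specification
#'
#' Defines the regular planar grid on which environmental statistics are
#' computed and habitat memberships are predicted. The study design uses a
#' 2.5 x 2.5 km grid; cells are referenced by (row, col) with row 1 at the
#' southern edge, column 1 at the western edge, and coordinates in km
#' (x increasing east, y increasing north). `origin` is the lower-left corner
#' of cell (1, 1); cell centers sit at `origin + (index - 0.5) * cell_size`.
#'
#' @param origin numeric length-2, lower-left corner (x, y) in km.
#' @param cell_size cell edge length in km (default 2.5).
#' @param n_rows,n_cols grid dimensions.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size = 2.5, n_rows, n_cols) {
  stopifnot(length(origin) == 2, is.numeric(origin))
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("cell_size must be a single positive number")
  }
  stopifnot(n_rows >= 1, n_cols >= 1)
  structure(
    list(origin = as.numeric(origin), cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, cell %.3g km, origin (%g, %g) km\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param spec a [grid_spec()].
#' @return data.frame with columns row, col, x_km, y_km (row-major order).
#' @export
grid_cell_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  rows <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  cols <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  data.frame(
    row = rows, col = cols,
    x_km = spec$origin[1] + (cols - 0.5) * spec$cell_size,
    y_km = spec$origin[2] + (rows - 0.5) * spec$cell_size
  )
}

# Map planar coordinates to (row, col); points outside the grid get NA.
# Points exactly on an interior cell boundary belong to the higher-index cell
# (nearest-center convention resolves ties toward the north-east neighbour).
grid_cell_index <- function(spec, x, y) {
  col <- floor((x - spec$origin[1]) / spec$cell_size) + 1L
  row <- floor((y - spec$origin[2]) / spec$cell_size) + 1L
  # points on the outer east/north boundary belong to the last cell
  col[x == spec$origin[1] + spec$n_cols * spec$cell_size] <- spec$n_cols
  row[y == spec$origin[2] + spec$n_rows * spec$cell_size] <- spec$n_rows
  bad <- col < 1L | col > spec$n_cols | row < 1L | row > spec$n_rows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Environmental grid layer
#'
#' One gridded statistic (e.g. yearly median or p95 - p5 range of a variable at
#' surface or bottom) on an analysis grid. Values are stored as an
#' n_rows x n_cols matrix (row 1 = southern edge); NA marks missing cells.
#'
#' @param spec a [grid_spec()].
#' @param values numeric matrix `n_rows x n_cols` (NA = missing), or a single
#'   number recycled over the grid.
#' @param variable variable acronym (e.g. "TEMP", "SAL", "PHOS").
#' @param statistic "median" or "range".
#' @param layer "surface", "bottom" or "static" (bathymetry, velocities).
#' @param period "winter", "spring", "summer", "autumn" or "yearly".
#' @return a `grid_layer` object.
#' @export
grid_layer <- function(spec, values, variable = "VAR", statistic = "median",
                       layer = "surface", period = "yearly") {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1) values <- matrix(values, spec$n_rows, spec$n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_rows, spec$n_cols))) {
    stop("values must be a ", spec$n_rows, " x ", spec$n_cols, " matrix")
  }
  statistic <- match.arg(statistic, c("median", "range"))
  if (statistic == "range" && any(values < 0, na.rm = TRUE)) {
    stop("range layers must be non-negative wherever non-missing")
  }
  structure(
    list(spec = spec, values = values, variable = variable,
         statistic = statistic, layer = layer, period = period),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat(sprintf("grid_layer %s [%s, %s, %s]: %d/%d cells populated\n",
              x$variable, x$statistic, x$layer, x$period,
              n_ok, length(x$values)))
  invisible(x)
}

layer_id <- function(layer) {
  paste(layer$variable, layer$statistic, layer$layer, layer$period, sep = ".")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Extract layer values at station positions
#'
#' Returns the value of the grid cell containing each station (the habitat
#' model is fitted on cell values so that sites sharing a 2.5 km cell share
#' predictors). Stations outside the grid are flagged with NA rather than
#' raising an error.
#'
#' @param layer a [grid_layer()].
#' @param stations data.frame with columns `x_km`, `y_km`.
#' @return numeric vector, one value per station (NA when the station falls
#'   outside the grid or in a missing cell).
#' @export
extract_at_sites <- function(layer, stations) {
  stopifnot(inherits(layer, "grid_layer"))
  idx <- grid_cell_index(layer$spec, stations$x_km, stations$y_km)
  out <- rep(NA_real_, nrow(stations))
  ok <- !is.na(idx$row)
  out[ok] <- layer$values[cbind(idx$row[ok], idx$col[ok])]
  if (any(!ok)) {
    warning(sum(!ok), " station(s) outside the grid; values set to NA")
  }
  out
}

#' Write a grid layer as an ESRI ASCII raster
#'
#' Plain-text `.asc` format readable by any GIS: a 6-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows of
#' values north-to-south.
#'
#' @param layer a [grid_layer()].
#' @param path output file path.
#' @param nodata sentinel written for missing cells (default -9999).
#' @export
write_esri_ascii <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "grid_layer"))
  s <- layer$spec
  vals <- layer$values
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", s$n_cols),
    sprintf("nrows %d", s$n_rows),
    sprintf("xllcorner %.10g", s$origin[1]),
    sprintf("yllcorner %.10g", s$origin[2]),
    sprintf("cellsize %.10g", s$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  # ESRI ASCII rows run north to south; internal storage has row 1 south
  for (r in rev(seq_len(s$n_rows))) {
    writeLines(paste(formatC(vals[r, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster into a grid layer
#'
#' @param path `.asc` file written by [write_esri_ascii()] or a GIS.
#' @inheritParams grid_layer
#' @return a [grid_layer()].
#' @export
read_esri_ascii <- function(path, variable = "VAR", statistic = "median",
                            layer = "surface", period = "yearly") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  vals <- matrix(NA_real_, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    row_vals <- as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]])
    vals[n_rows - i + 1L, ] <- row_vals
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  spec <- grid_spec(origin = c(hdr$xllcorner, hdr$yllcorner),
                    cell_size = hdr$cellsize, n_rows = n_rows, n_cols = n_cols)
  grid_layer(spec, vals, variable = variable, statistic = statistic,
             layer = layer, period = period)
}
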