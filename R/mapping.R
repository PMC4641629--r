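#' Predict fuzzy habitat memberships over a grid
#'
#' Projects a fitted RDA model onto gridded predictor layers: per cell, the
#' predictor values are standardized with the model's stored constants,
#' multiplied by the canonical coefficients and shifted by the response
#' means, giving predictions on the transformed (Hellinger / square-root)
#' scale. These are back-transformed by squaring, clipped to [0, 1] and,
#' by default, renormalized so each cell's memberships sum to 1. Cells
#' missing any selected predictor are missing in every output layer (no
#' imputation). Cells whose standardized predictors leave the training range
#' by more than `extrapolation_sd` standard deviations are flagged in an
#' extrapolation mask, not suppressed.
#'
#' @param model an `rda_model` fitted on Hellinger-transformed memberships.
#' @param layers named list of [grid_layer()]s; must contain one entry per
#'   model variable (matched by `names(layers)` or by layer variable id).
#' @param renormalize rescale non-missing cells to unit membership sum
#'   (default TRUE).
#' @param extrapolation_sd threshold (in training SDs) for the extrapolation
#'   mask (default 3).
#' @return object of class `habitat_map`: `spec`, `memberships` (list of
#'   cluster matrices in [0,1]), `raw` (transformed-scale predictions),
#'   `extrapolation` (logical matrix), `model_variables`.
#' @export
predict_memberships <- function(model, layers, renormalize = TRUE,
                                extrapolation_sd = 3) {
  stopifnot(inherits(model, "rda_model"))
  vars <- model$variables
  miss <- setdiff(vars, names(layers))
  if (length(miss)) {
    stop("missing predictor layer(s): ", paste(miss, collapse = ", "))
  }
  layers <- layers[vars]
  spec <- layers[[1]]$spec
  for (l in layers) {
    if (!same_grid(l$spec, spec)) {
      stop("grid mismatch: layer ", layer_id(l),
           " is not on the shared grid")
    }
  }
  n_cell <- spec$n_rows * spec$n_cols
  Xg <- vapply(layers, function(l) as.numeric(t(l$values)), numeric(n_cell))
  colnames(Xg) <- vars  # row-major cell order
  ok <- stats::complete.cases(Xg)
  q <- length(model$responses)
  pred_raw <- matrix(NA_real_, n_cell, q,
                     dimnames = list(NULL, model$responses))
  extrap <- rep(NA, n_cell)
  if (any(ok)) {
    Z <- sweep(sweep(Xg[ok, , drop = FALSE], 2, model$x_center), 2,
               model$x_scale, "/")
    pred_raw[ok, ] <- Z %*% model$coefficients +
      rep(model$y_center, each = sum(ok))
    extrap[ok] <- apply(abs(Z) > extrapolation_sd, 1, any)
  }
  memb <- pred_raw^2        # inverse of the square-root membership scale
  memb[pred_raw < 0] <- 0   # negative transformed predictions mean "absent"
  memb[memb > 1] <- 1
  if (renormalize) {
    rs <- rowSums(memb)
    pos <- ok & !is.na(rs) & rs > 0
    memb[pos, ] <- memb[pos, , drop = FALSE] / rs[pos]
  }
  to_mat <- function(v) matrix(v, spec$n_rows, spec$n_cols, byrow = TRUE)
  structure(
    list(
      spec = spec,
      memberships = stats::setNames(
        lapply(seq_len(q), function(j) to_mat(memb[, j])), model$responses),
      raw = stats::setNames(
        lapply(seq_len(q), function(j) to_mat(pred_raw[, j])), model$responses),
      extrapolation = to_mat(extrap),
      model_variables = vars,
      renormalized = renormalize
    ),
    class = "habitat_map"
  )
}

#' @export
print.habitat_map <- function(x, ...) {
  n_ok <- sum(!is.na(x$memberships[[1]]))
  cat(sprintf("habitat_map: %d clusters on %d x %d grid, %d/%d cells predicted\n",
              length(x$memberships), x$spec$n_rows, x$spec$n_cols,
              n_ok, length(x$memberships[[1]])))
  invisible(x)
}

#' Summarize a predicted habitat map
#'
#' Area fractions (share of non-missing cells where each cluster has the
#' strictly highest membership) and a dominance raster of the argmax cluster,
#' with exact ties flagged (code 0) rather than broken by column order.
#'
#' @param map a `habitat_map`.
#' @return list: `area_fraction` (named per cluster; ties excluded from all),
#'   `tie_fraction`, `dominance` ([grid_layer()]-like integer matrix, 0 = tie,
#'   j = cluster j dominant, NA = missing), `n_cells` (non-missing count).
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  q <- length(map$memberships)
  M <- vapply(map$memberships, function(m) as.numeric(t(m)),
              numeric(map$spec$n_rows * map$spec$n_cols))
  ok <- stats::complete.cases(M)
  if (!any(ok)) {
    return(list(area_fraction = stats::setNames(numeric(q), names(map$memberships)),
                tie_fraction = NA_real_, dominance = NULL, n_cells = 0L))
  }
  dom <- rep(NA_integer_, nrow(M))
  dom[ok] <- vapply(which(ok), function(i) {
    a <- argmax_with_ties(M[i, ])
    if (is.na(a)) 0L else a
  }, integer(1))
  n_ok <- sum(ok)
  frac <- vapply(seq_len(q), function(j) sum(dom == j, na.rm = TRUE) / n_ok,
                 numeric(1))
  names(frac) <- names(map$memberships)
  list(
    area_fraction = frac,
    tie_fraction = sum(dom == 0L, na.rm = TRUE) / n_ok,
    dominance = matrix(dom, map$spec$n_rows, map$spec$n_cols, byrow = TRUE),
    n_cells = n_ok
  )
}

#' Write all layers of a habitat map as ESRI ASCII rasters
#'
#' One file per cluster membership layer plus the dominance and
#' extrapolation-mask layers.
#'
#' @param map a `habitat_map`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisible character vector of written paths.
#' @export
write_habitat_map <- function(map, dir, prefix = "habitat") {
  stopifnot(inherits(map, "habitat_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(map$memberships)) {
    lay <- grid_layer(map$spec, map$memberships[[nm]], variable = nm,
                      statistic = "median", layer = "static", period = "yearly")
    p <- file.path(dir, paste0(prefix, "_", nm, ".asc"))
    write_esri_ascii(lay, p)
    paths <- c(paths, p)
  }
  sm <- map_summary(map)
  if (!is.null(sm$dominance)) {
    dl <- grid_layer(map$spec, sm$dominance, variable = "dominance",
                     statistic = "median", layer = "static", period = "yearly")
    p <- file.path(dir, paste0(prefix, "_dominance.asc"))
    write_esri_ascii(dl, p)
    paths <- c(paths, p)
  }
  ex <- map$extrapolation
  storage.mode(ex) <- "double"
  el <- grid_layer(map$spec, ex, variable = "extrapolation",
                   statistic = "median", layer = "static", period = "yearly")
  p <- file.path(dir, paste0(prefix, "_extrapolation.asc"))
  write_esri_ascii(el, p)
  invisible(c(paths, p))
}
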