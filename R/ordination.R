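#' Hellinger transformation
#'
#' Square root of the row-relative abundance: `y' = sqrt(y / rowsum)`. Each
#' transformed row has unit Euclidean norm, which makes Euclidean-based
#' ordination (RDA) appropriate for community-style data and avoids the
#' species-abundance paradox. For a membership matrix (rows already summing
#' to 1) this reduces to the elementwise square root.
#'
#' @param Y nonnegative numeric matrix (sites x taxa or sites x clusters).
#' @return transformed matrix of the same shape.
#' @export
hellinger_transform <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("Hellinger transformation requires nonnegative values")
  rs <- rowSums(Y)
  if (any(rs <= 0)) {
    bad <- rownames(Y)[rs <= 0] %||% which(rs <= 0)
    stop("zero-sum row(s): ", paste(bad, collapse = ", "))
  }
  sqrt(sweep(Y, 1, rs, "/"))
}

#' Ezekiel-adjusted R squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`; penalizes explained variance for
#' the number of predictors and can be negative.
#'
#' @param r2 unadjusted R squared.
#' @param n number of observations.
#' @param p number of predictors.
#' @return adjusted R squared.
#' @export
adj_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R2 undefined for n <= p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination: multivariate least-squares regression of the
#' (centered) response matrix on centered, unit-scaled predictors, followed by
#' an eigen-decomposition of the fitted values. Canonical coefficients are
#' stored together with the predictor centering/scaling constants and response
#' means so the fitted model can be projected onto new predictor values
#' (e.g. grid cells).
#'
#' @param Y numeric response matrix (n x q), e.g. Hellinger-transformed
#'   membership grades.
#' @param X predictor matrix or data.frame (n x p), mixed units allowed
#'   (standardized internally).
#' @param scale_x standardize predictors to unit variance (default TRUE).
#' @return object of class `rda_model`: `coefficients` (p x q, on
#'   standardized predictors), `eigenvalues` (constrained), `residual_eigenvalues`,
#'   `total_variance`, `r2`, `adj_r2`, `axis_r2`, `axis_adj_r2`,
#'   `response_axis_fractions` (per-response share of variance by axis),
#'   `x_center`, `x_scale`, `y_center`, `fitted`, `site_scores`, `axis_p` (filled by
#'   [permtest_axes()]).
#' @export
rda_fit <- function(Y, X, scale_x = TRUE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  if (nrow(X) != n) stop("Y and X must have the same number of rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))
  if (n <= p + 1) {
    if (n <= p) stop("more predictors than residual degrees of freedom (p >= n)")
    warning("model is saturated (p = n - 1): constrained fit leaves no residual df")
  }
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  x_scale <- if (scale_x) apply(Xc, 2, stats::sd) else rep(1, p)
  if (any(x_scale == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[x_scale == 0], collapse = ", "))
  }
  Xs <- sweep(Xc, 2, x_scale, "/")
  qx <- qr(Xs)
  if (qx$rank < p) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient predictors; linearly dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)
  B <- qr.coef(qx, Yc)
  Yhat <- Xs %*% B
  ss_tot <- sum(Yc^2)
  ss_exp <- sum(Yhat^2)
  r2 <- ss_exp / ss_tot
  sv <- svd(Yhat, nu = 0)
  tol_ev <- max(sv$d) * 1e-12
  keep <- sv$d > tol_ev
  eig <- (sv$d[keep]^2) / (n - 1)
  V <- sv$v[, keep, drop = FALSE]
  Yres <- Yc - Yhat
  sv_res <- svd(Yres, nu = 0, nv = 0)$d
  res_eig <- (sv_res[sv_res > max(sv_res[1], 1) * 1e-12]^2) / (n - 1)
  total_var <- ss_tot / (n - 1)
  a_r2 <- if (n > p + 1) adj_r2(r2, n, p) else NA_real_
  axis_r2 <- eig / total_var
  # per-response variance split over constrained axes: response j's share on
  # axis a is (V[j,a] * d_a)^2 / ((n-1) * var_j)
  scores <- Yhat %*% V
  var_y <- colSums(Yc^2) / (n - 1)
  frac <- t((V^2) * rep((sv$d[keep]^2) / (n - 1), each = q)) / rep(var_y, each = sum(keep))
  frac <- t(frac)
  dimnames(frac) <- list(colnames(Y) %||% paste0("Y", seq_len(q)),
                         paste0("RDA", seq_len(sum(keep))))
  colnames(scores) <- paste0("RDA", seq_len(ncol(scores)))
  structure(
    list(coefficients = B, eigenvalues = eig, residual_eigenvalues = res_eig,
         total_variance = total_var, r2 = r2, adj_r2 = a_r2,
         axis_r2 = axis_r2, axis_adj_r2 = axis_r2 * (a_r2 / r2),
         response_axis_fractions = frac,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         fitted = Yhat, site_scores = scores, axis_loadings = V,
         n = n, p = p, variables = colnames(X), axis_p = NULL,
         responses = colnames(Y) %||% paste0("Y", seq_len(q))),
    class = "rda_model"
  )
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("RDA: %d sites, %d predictors, %d responses\n",
              x$n, x$p, length(x$responses)))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f\n", x$r2, x$adj_r2))
  ax <- sprintf("%.3f", x$axis_adj_r2)
  cat("  per-axis adjusted R2: ", paste(ax, collapse = ", "), "\n", sep = "")
  if (!is.null(x$axis_p)) {
    cat("  axis p-values: ", paste(format(x$axis_p), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Predict transformed responses from an RDA model
#'
#' Applies the stored canonical coefficients to new predictor values:
#' standardize with the training centering/scaling constants, multiply by the
#' coefficients, and add the response means. Output is on the (transformed)
#' response scale of the training Y.
#'
#' @param object an `rda_model`.
#' @param newdata matrix/data.frame with the model's predictor columns.
#' @param ... unused.
#' @return matrix of predicted transformed responses.
#' @export
predict.rda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$variables, colnames(newdata))
  if (length(miss)) stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  Xs <- sweep(sweep(newdata[, object$variables, drop = FALSE], 2,
                    object$x_center), 2, object$x_scale, "/")
  Xs %*% object$coefficients + rep(object$y_center, each = nrow(Xs))
}

# Internal fast engine for permutation tests: orthonormal basis of the
# centered/scaled predictor space.
ortho_basis <- function(X, scale_x = TRUE) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  if (scale_x) {
    s <- apply(Xc, 2, stats::sd)
    s[s == 0] <- 1
    Xc <- sweep(Xc, 2, s, "/")
  }
  qx <- qr(Xc)
  list(Q = qr.Q(qx)[, seq_len(qx$rank), drop = FALSE], rank = qx$rank)
}

first_eig_and_rss <- function(Q, Yc) {
  Yhat <- Q %*% crossprod(Q, Yc)
  d1 <- svd(Yhat, nu = 0, nv = 0)$d[1]
  # a numerically perfect fit can leave a tiny negative residual sum
  list(lambda1 = d1^2, ss_exp = sum(Yhat^2),
       rss = max(sum(Yc^2) - sum(Yhat^2), 0))
}

#' Sequential permutation tests of RDA axes
#'
#' Tests each constrained axis in sequence: axis j is tested with the
#' preceding axes' site scores partialled out of both the response and the
#' predictors. The statistic is a pseudo-F of the axis eigenvalue against the
#' full-model residual variance; the null distribution comes from `n_perm`
#' unrestricted row permutations of the (residualized) response. P-values use
#' add-one smoothing: `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param Y response matrix (will be centered).
#' @param X predictor matrix/data.frame.
#' @param n_perm number of permutations (study convention 999).
#' @param seed RNG seed for the permutation stream.
#' @param n_axes number of leading axes to test (default: all constrained).
#' @return numeric vector of per-axis p-values.
#' @export
permtest_axes <- function(Y, X, n_perm = 999, seed = 1L, n_axes = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  fit <- rda_fit(Y, X)
  n_ax <- length(fit$eigenvalues)
  if (!is.null(n_axes)) n_ax <- min(n_ax, n_axes)
  df_res <- n - 1 - fit$p
  if (df_res < 1) df_res <- 1
  pvals <- numeric(n_ax)
  Yc <- sweep(Y, 2, colMeans(Y))
  with_seed(seed, {
    for (j in seq_len(n_ax)) {
      if (j == 1) {
        Yr <- Yc
        Xr <- X
      } else {
        Z <- fit$site_scores[, seq_len(j - 1), drop = FALSE]
        qz <- qr(cbind(1, Z))
        Yr <- qr.resid(qz, Yc)
        Xr <- qr.resid(qz, sweep(X, 2, colMeans(X)))
      }
      ob <- ortho_basis(Xr, scale_x = (j == 1))
      obs <- first_eig_and_rss(ob$Q, Yr)
      f_obs <- obs$lambda1 / (obs$rss / df_res)
      count <- 0L
      for (b in seq_len(n_perm)) {
        Yp <- Yr[sample.int(n), , drop = FALSE]
        st <- first_eig_and_rss(ob$Q, Yp)
        f_perm <- st$lambda1 / (st$rss / df_res)
        if (f_perm >= f_obs) count <- count + 1L
      }
      pvals[j] <- (1 + count) / (1 + n_perm)
    }
  })
  names(pvals) <- paste0("RDA", seq_len(n_ax))
  pvals
}

#' Global permutation test of an RDA model
#'
#' Pseudo-F of the whole constrained fraction against residual variance,
#' with row permutations of the response.
#'
#' @inheritParams permtest_axes
#' @return list with `f`, `p_value`, `r2`, `adj_r2`.
#' @export
permtest_global <- function(Y, X, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  ob <- ortho_basis(X)
  p <- ob$rank
  df_res <- max(n - 1 - p, 1)
  ss_tot <- sum(Yc^2)
  fit_ss <- function(Ym) {
    Yhat <- ob$Q %*% crossprod(ob$Q, Ym)
    sum(Yhat^2)
  }
  ss_exp <- fit_ss(Yc)
  f_obs <- (ss_exp / p) / (max(ss_tot - ss_exp, 0) / df_res)
  count <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      ssb <- fit_ss(Yc[sample.int(n), , drop = FALSE])
      f_b <- (ssb / p) / ((ss_tot - ssb) / df_res)
      if (f_b >= f_obs) count <- count + 1L
    }
  })
  r2 <- ss_exp / ss_tot
  list(f = f_obs, p_value = (1 + count) / (1 + n_perm),
       r2 = r2, adj_r2 = adj_r2(r2, n, p))
}

#' Forward selection with the double stopping criterion
#'
#' Selects predictors for an RDA in a forward stepwise manner with two
#' safeguards against inflation of explained variance: (i) the global model
#' with all candidates must itself be significant before anything is
#' selected, and (ii) selection stops as soon as the best remaining
#' candidate's partial permutation p-value exceeds `alpha` or the adjusted R
#' squared of the selected set would exceed that of the global model (the
#' ceiling).
#'
#' @param Y response matrix.
#' @param X candidate predictor matrix/data.frame.
#' @param alpha significance level for the global and partial tests.
#' @param n_perm permutations per test.
#' @param seed RNG seed.
#' @return list: `selected` (character vector, possibly empty), `adj_r2_path`
#'   (cumulative adjusted R2 after each inclusion), `global` (global test
#'   result), `p_values` (partial p-value at each inclusion), `stopped_by`
#'   ("global", "alpha", "adjr2" or "exhausted").
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_perm = 999, seed = 1L) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_tot <- sum(Yc^2)
  global <- permtest_global(Y, X, n_perm = n_perm, seed = substream(seed, "perm"))
  out <- list(selected = character(0), adj_r2_path = numeric(0),
              global = global, p_values = numeric(0), stopped_by = NULL)
  if (global$p_value > alpha) {
    out$stopped_by <- "global"
    return(out)
  }
  ceiling_adj <- global$adj_r2
  candidates <- colnames(X)
  selected <- character(0)
  warned_collinear <- FALSE
  with_seed(substream(seed, "select"), {
    repeat {
      remaining <- setdiff(candidates, selected)
      if (!length(remaining)) { out$stopped_by <- "exhausted"; break }
      # R2 of selected + each candidate
      r2_new <- rep(NA_real_, length(remaining))
      names(r2_new) <- remaining
      for (v in remaining) {
        Xtry <- X[, c(selected, v), drop = FALSE]
        ob <- ortho_basis(Xtry)
        if (ob$rank < length(selected) + 1L) {
          if (!warned_collinear) {
            warning("candidate(s) collinear with the selected set skipped (e.g. ", v, ")")
            warned_collinear <- TRUE
          }
          next
        }
        Yhat <- ob$Q %*% crossprod(ob$Q, Yc)
        r2_new[v] <- sum(Yhat^2) / ss_tot
      }
      if (all(is.na(r2_new))) { out$stopped_by <- "exhausted"; break }
      best <- names(which.max(r2_new))
      # partial permutation test of `best` given `selected`
      if (length(selected)) {
        qz <- qr(cbind(1, X[, selected, drop = FALSE]))
        Yr <- qr.resid(qz, Yc)
        xr <- qr.resid(qz, X[, best])
      } else {
        Yr <- Yc
        xr <- X[, best] - mean(X[, best])
      }
      u <- xr / sqrt(sum(xr^2))
      df_res <- n - 1 - length(selected) - 1L
      ss_r <- sum(Yr^2)
      proj_ss <- function(Ym) sum((crossprod(u, Ym))^2)
      ss_obs <- proj_ss(Yr)
      f_obs <- ss_obs / (max(ss_r - ss_obs, 0) / df_res)
      count <- 0L
      for (b in seq_len(n_perm)) {
        Yp <- Yr[sample.int(n), , drop = FALSE]
        ssb <- proj_ss(Yp)
        f_b <- ssb / ((ss_r - ssb) / df_res)
        if (f_b >= f_obs) count <- count + 1L
      }
      p_val <- (1 + count) / (1 + n_perm)
      if (p_val > alpha) { out$stopped_by <- "alpha"; break }
      selected <- c(selected, best)
      new_adj <- adj_r2(r2_new[best], n, length(selected))
      out$p_values <- c(out$p_values, stats::setNames(p_val, best))
      out$adj_r2_path <- c(out$adj_r2_path, stats::setNames(new_adj, best))
      # second stopping rule: once the selected set's cumulative adjusted R2
      # reaches the global ceiling there is nothing honest left to add
      if (new_adj > ceiling_adj) { out$stopped_by <- "adjr2"; break }
    }
  })
  out$selected <- selected
  out
}

#' Two-step subset selection and final RDA model
#'
#' The study-design procedure for many candidate predictors and few sites:
#' the candidates are split into subsets (surface water quality, bottom water
#' quality, hydrodynamics), each subset gets its own RDA with axis tests and
#' forward selection, and the union of the selected variables plus depth
#' forms the final model. Depth is forced into the final model, not selected.
#' Optionally a further forward selection over the final predictors (depth
#' now a regular candidate) is reported as a parsimonious alternative; the
#' union+depth model remains the model used for prediction.
#'
#' @param Y response matrix (e.g. Hellinger-transformed memberships).
#' @param groups named list of candidate predictor matrices (one per subset).
#' @param depth numeric vector (or 1-column matrix) of site depths, forced
#'   into the final model.
#' @param alpha,n_perm,seed forwarded to the selection and tests.
#' @param reduce also run the second forward selection on the final
#'   predictors (default TRUE).
#' @return list: `final` (`rda_model` with `axis_p` filled), `selection`
#'   (per-group [forward_select()] results), `subset_models` (per-group
#'   `rda_model`s), `reduced` (second-selection result and model or NULL),
#'   `predictors` (final predictor matrix).
#' @export
two_step_subset_selection <- function(Y, groups, depth, alpha = 0.05,
                                      n_perm = 999, seed = 1L, reduce = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list")
  }
  Y <- as.matrix(Y)
  depth <- as.matrix(depth)
  colnames(depth) <- colnames(depth) %||% "Depth"
  if (ncol(depth) != 1) colnames(depth) <- "Depth"
  selection <- list(); subset_models <- list(); union_cols <- list()
  gi <- 0L
  for (g in names(groups)) {
    gi <- gi + 1L
    Xg <- as.matrix(groups[[g]])
    sel <- forward_select(Y, Xg, alpha = alpha, n_perm = n_perm,
                          seed = seed + gi)
    selection[[g]] <- sel
    subset_models[[g]] <- rda_fit(Y, Xg)
    subset_models[[g]]$axis_p <- permtest_axes(Y, Xg, n_perm = n_perm,
                                               seed = seed + 100L + gi)
    if (length(sel$selected)) {
      union_cols[[g]] <- Xg[, sel$selected, drop = FALSE]
    }
  }
  if (!length(union_cols)) {
    warning("no variable selected in any group; final model is depth-only")
    Xfinal <- depth
  } else {
    Xfinal <- cbind(do.call(cbind, union_cols), depth)
  }
  final <- rda_fit(Y, Xfinal)
  final$axis_p <- permtest_axes(Y, Xfinal, n_perm = n_perm,
                                seed = seed + 900L)
  reduced <- NULL
  if (reduce && ncol(Xfinal) > 1) {
    sel2 <- forward_select(Y, Xfinal, alpha = alpha, n_perm = n_perm,
                           seed = seed + 901L)
    if (length(sel2$selected)) {
      m2 <- rda_fit(Y, Xfinal[, sel2$selected, drop = FALSE])
      m2$axis_p <- permtest_axes(Y, Xfinal[, sel2$selected, drop = FALSE],
                                 n_perm = n_perm, seed = seed + 902L)
      reduced <- list(selection = sel2, model = m2)
    } else {
      reduced <- list(selection = sel2, model = NULL)
    }
  }
  list(final = final, selection = selection, subset_models = subset_models,
       reduced = reduced, predictors = Xfinal)
}

#' Variation partitioning over predictor groups
#'
#' Decomposes the adjusted R squared of the final model among 2-4 named
#' predictor groups: marginal fractions for every union of groups, and
#' conditional fractions by the subtraction identity
#' `adjR2(A | B) = adjR2(A + B) - adjR2(B)`. The residual fraction is
#' `1 - adjR2(all groups)`.
#'
#' @param Y response matrix.
#' @param groups named list of 2-4 predictor matrices.
#' @return data.frame of class `partition_table` with columns `term` and
#'   `adj_r2`, ordered: single groups, pairs, triples, all, residuals,
#'   conditionals on 1, 2 and 3 groups.
#' @export
variation_partition <- function(Y, groups) {
  g <- length(groups)
  if (g < 2 || g > 4) stop("variation partitioning supports 2-4 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list")
  }
  Y <- as.matrix(Y)
  n <- nrow(Y)
  nm <- names(groups)
  subsets <- lapply(seq_len(2^g - 1), function(b) which(bitwAnd(b, 2^(seq_len(g) - 1)) > 0))
  union_adj <- numeric(0)
  for (s in subsets) {
    Xu <- do.call(cbind, lapply(groups[s], as.matrix))
    p_tot <- ncol(Xu)
    if (n <= p_tot + 1) stop("saturated union: ", paste(nm[s], collapse = "+"))
    fit <- rda_fit(Y, Xu)
    union_adj[paste(nm[s], collapse = "+")] <- fit$adj_r2
  }
  partition_identities(union_adj, nm)
}

#' Conditional fractions from marginal adjusted R squared values
#'
#' Computes a full partition table from pre-computed adjusted R squared
#' values of group unions via the subtraction identity -- usable directly on
#' published marginal fractions as well as on fitted ones.
#'
#' @param union_adj named numeric vector; names are group unions like
#'   `"Surface"`, `"Surface+Bottom"` (order within a name is free).
#' @param group_names the single-group names, in display order; default:
#'   derived from the single-group entries of `union_adj`.
#' @return data.frame of class `partition_table` (see [variation_partition()]).
#' @export
partition_identities <- function(union_adj, group_names = NULL) {
  parts <- strsplit(names(union_adj), "+", fixed = TRUE)
  canon <- function(x) paste(sort(x), collapse = "+")
  lookup <- stats::setNames(as.numeric(union_adj),
                            vapply(parts, canon, character(1)))
  if (is.null(group_names)) {
    group_names <- names(union_adj)[lengths(parts) == 1]
  }
  g <- length(group_names)
  get_u <- function(set) {
    key <- canon(set)
    if (!key %in% names(lookup)) return(NA_real_)
    lookup[[key]]
  }
  rows <- list()
  add <- function(term, value) rows[[length(rows) + 1L]] <<- data.frame(
    term = term, adj_r2 = value, stringsAsFactors = FALSE)
  for (a in group_names) add(a, get_u(a))
  sizes <- if (g >= 2) 2:g else integer(0)
  for (sz in sizes) {
    combos <- utils::combn(group_names, sz, simplify = FALSE)
    for (cc in combos) {
      term <- paste(cc, collapse = "+")
      if (sz == g) term <- "All" else term <- term
      add(term, get_u(cc))
    }
  }
  all_val <- get_u(group_names)
  add("Residuals", 1 - all_val)
  for (cond_size in seq_len(g - 1)) {
    for (a in group_names) {
      others <- setdiff(group_names, a)
      if (length(others) < cond_size) next
      for (cond in utils::combn(others, cond_size, simplify = FALSE)) {
        u_ab <- get_u(c(a, cond))
        u_b <- get_u(cond)
        add(paste0(a, "|", paste(cond, collapse = "+")), u_ab - u_b)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("partition_table", "data.frame")
  out
}

#' Look up a partition-table entry
#'
#' @param pt a `partition_table`.
#' @param term row name such as `"Surface|Bottom"` or `"All"`.
#' @return the adjusted R squared of that term.
#' @export
partition_term <- function(pt, term) {
  hit <- match(term, pt$term)
  if (is.na(hit)) stop("no such partition term: ", term)
  pt$adj_r2[hit]
}
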