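#' Fuzzy k-means clustering of sites
#'
#' Partitions sites into `k` overlapping clusters by alternating optimization
#' of the fuzzy objective
#' \deqn{J = \sum_i \sum_h u_{ih}^m \, \|x_i - c_h\|^2}
#' with membership update \eqn{u_{ih} = 1 / \sum_g (d_{ih}/d_{ig})^{2/(m-1)}}
#' and centroid update \eqn{c_h = \sum_i u_{ih}^m x_i / \sum_i u_{ih}^m}.
#' Sites coinciding with a centroid get crisp membership (zero-distance rule).
#' The best solution over `n_init` random row-stochastic membership
#' initializations is returned; given the same `seed`, results are
#' reproducible bit for bit, and the initialization stream is shared across
#' `n_init` values (the first `n` starts of a longer run equal a shorter run),
#' so the best objective is monotone non-increasing in `n_init`.
#'
#' @param X numeric matrix, sites x features.
#' @param k number of clusters (>= 2).
#' @param m fuzziness exponent (> 1; 2 is the conventional choice).
#' @param n_init number of random initializations (the study design uses 1000).
#' @param max_iter maximum alternating-optimization iterations per start.
#' @param tol relative objective change |dJ|/J declaring convergence.
#' @param seed integer seed controlling the initialization stream.
#' @param init optional sites x k membership matrix used as the single
#'   explicit start (overrides `n_init`).
#' @return object of class `fkm_fit`: `memberships` (sites x k, rows sum to
#'   1), `centroids` (k x features), `objective` (best J), `m`, `iterations`,
#'   `objective_trace` (J per iteration of the winning start), `objective_by_init`.
#' @export
fkm_fit <- function(X, k, m = 2, n_init = 1000, max_iter = 500, tol = 1e-9,
                    seed = 1L, init = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  if (k < 2) stop("k must be >= 2")
  if (m <= 1) stop("fuzziness m must be > 1")
  n <- nrow(X)
  if (nrow(unique(as.data.frame(X))) < k) {
    stop("degenerate input: fewer than k distinct rows")
  }
  run_one <- function(U0) {
    U <- U0
    J_prev <- Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      Um <- U^m
      w <- colSums(Um)
      C <- sweep(crossprod(Um, X), 1, w, "/")
      D2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(C) +
        outer(rep(1, n), rowSums(C^2))
      D2[D2 < 0] <- 0
      U <- membership_from_d2(D2, m)
      J <- sum(U^m * D2)
      trace <- c(trace, J)
      if (is.finite(J_prev) && abs(J_prev - J) <= tol * max(J, .Machine$double.eps)) {
        J_prev <- J
        break
      }
      J_prev <- J
    }
    list(U = U, C = C, J = J_prev, trace = trace, iterations = length(trace))
  }
  if (!is.null(init)) {
    init <- as.matrix(init)
    stopifnot(nrow(init) == n, ncol(init) == k)
    best <- run_one(init)
    J_by_init <- best$J
  } else {
    best <- NULL
    J_by_init <- numeric(n_init)
    with_seed(seed, {
      for (s in seq_len(n_init)) {
        U0 <- matrix(stats::runif(n * k), n, k)
        U0 <- U0 / rowSums(U0)
        res <- run_one(U0)
        J_by_init[s] <- res$J
        if (is.null(best) || res$J < best$J) best <- res
      }
    })
  }
  rownames(best$U) <- rownames(X)
  colnames(best$U) <- paste0("cluster_", seq_len(k))
  rownames(best$C) <- colnames(best$U)
  structure(
    list(memberships = best$U, centroids = best$C, objective = best$J,
         m = m, k = k, iterations = best$iterations,
         objective_trace = best$trace, objective_by_init = J_by_init),
    class = "fkm_fit"
  )
}

# Membership update from squared distances, honoring the zero-distance rule.
membership_from_d2 <- function(D2, m) {
  n <- nrow(D2); k <- ncol(D2)
  expo <- -1 / (m - 1)
  U <- matrix(0, n, k)
  zero_rows <- which(apply(D2, 1, function(r) any(r == 0)))
  pos_rows <- setdiff(seq_len(n), zero_rows)
  if (length(pos_rows)) {
    W <- D2[pos_rows, , drop = FALSE]^expo
    U[pos_rows, ] <- W / rowSums(W)
  }
  for (i in zero_rows) {
    z <- D2[i, ] == 0
    U[i, z] <- 1 / sum(z)
  }
  U
}

#' @export
print.fkm_fit <- function(x, ...) {
  cat(sprintf("fuzzy k-means: %d sites, k = %d, m = %g, J = %.6g (%d iterations)\n",
              nrow(x$memberships), x$k, x$m, x$objective, x$iterations))
  invisible(x)
}

#' Align fuzzy clusters with expert habitat labels
#'
#' Fuzzy k-means cluster order is arbitrary; this renames the membership
#' columns by the permutation that maximizes the number of sites whose
#' highest-membership cluster matches their expert label (exhaustive search
#' over the k! permutations). Columns are renamed `FKM_<label>`.
#'
#' @param U sites x k membership matrix (or an `fkm_fit`).
#' @param expert_labels per-site labels; the number of distinct labels must
#'   equal k.
#' @return the membership matrix with permuted, renamed columns; attribute
#'   `permutation` records the applied column order.
#' @export
align_clusters <- function(U, expert_labels) {
  if (inherits(U, "fkm_fit")) U <- U$memberships
  U <- as.matrix(U)
  k <- ncol(U)
  labels <- sort(unique(as.character(expert_labels)))
  if (length(labels) != k) {
    stop("number of distinct expert labels (", length(labels),
         ") must equal the number of clusters (", k, ")")
  }
  if (k > 5) stop("exhaustive alignment supported for k <= 5")
  perms <- perm_matrix(k)
  lab_idx <- match(as.character(expert_labels), labels)
  amax <- apply(U, 1, which.max)
  best <- NULL; best_hits <- -1L
  for (p in seq_len(nrow(perms))) {
    perm <- as.integer(perms[p, ])
    # column perm[j] of U becomes output column j (label j)
    hits <- sum(match(amax, perm) == lab_idx, na.rm = TRUE)
    if (hits > best_hits) { best_hits <- hits; best <- perm }
  }
  out <- U[, best, drop = FALSE]
  colnames(out) <- paste0("FKM_", labels)
  attr(out, "permutation") <- best
  attr(out, "matches") <- best_hits
  out
}

perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE]))
  }
  out
}

#' Sites whose fuzzy assignment disagrees with the expert label
#'
#' Compares the highest-membership cluster of each site with its expert
#' habitat label. Sites whose maximum membership is attained by more than one
#' cluster are reported as ties, not mismatches.
#'
#' @param U aligned membership matrix with `FKM_<label>` columns (see
#'   [align_clusters()]); site ids as rownames.
#' @param expert_labels per-site expert labels.
#' @return list with `mismatches` (character vector of site ids), `count`,
#'   and `ties` (site ids with non-unique maximum membership).
#' @export
mismatch_report <- function(U, expert_labels) {
  U <- as.matrix(U)
  labels <- sub("^FKM_", "", colnames(U))
  sites <- rownames(U) %||% as.character(seq_len(nrow(U)))
  amax <- apply(U, 1, argmax_with_ties)
  tie <- is.na(amax)
  mismatch <- !tie & labels[amax] != as.character(expert_labels)
  list(
    mismatches = sites[mismatch],
    count = sum(mismatch),
    ties = sites[tie]
  )
}

#' Membership-grade summary statistics
#'
#' Per-cluster counts of sites above a membership threshold, per-cluster
#' min/max membership, and the number of high-fuzziness sites (no membership
#' above the threshold). The `tie_rule` selects strict (`>`) or inclusive
#' (`>=`) threshold comparison -- printed membership tables are rounded, so
#' the two rules can genuinely differ.
#'
#' @param U membership matrix (sites x k).
#' @param threshold membership threshold in (0, 1); default 0.50.
#' @param tie_rule "strict" (count > threshold) or "inclusive" (>= threshold).
#' @return list: `counts` (named per-cluster), `range` (2 x k matrix of
#'   min/max), `high_fuzziness` (count of sites with max membership <=
#'   threshold under strict rule, < threshold under inclusive rule).
#' @export
membership_summary <- function(U, threshold = 0.50,
                               tie_rule = c("strict", "inclusive")) {
  if (inherits(U, "fkm_fit")) U <- U$memberships
  U <- as.matrix(U)
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1")
  }
  above <- if (tie_rule == "strict") U > threshold else U >= threshold
  counts <- colSums(above)
  rng <- apply(U, 2, range)
  rownames(rng) <- c("min", "max")
  row_max <- apply(U, 1, max)
  high_fuzz <- if (tie_rule == "strict") sum(row_max <= threshold)
               else sum(row_max < threshold)
  list(counts = counts, range = rng, high_fuzziness = high_fuzz,
       threshold = threshold, tie_rule = tie_rule)
}

#' Fuzzy objective across candidate cluster numbers
#'
#' Diagnostic only: reports the best objective J for a range of k so the
#' analyst can judge cluster-number sensitivity. The pipeline itself keeps k
#' fixed by the expert typology.
#'
#' @inheritParams fkm_fit
#' @param k_range integer vector of candidate cluster numbers.
#' @return data.frame with columns k and objective.
#' @export
fkm_k_profile <- function(X, k_range = 2:6, m = 2, n_init = 50, seed = 1L) {
  data.frame(
    k = k_range,
    objective = vapply(k_range, function(k) {
      fkm_fit(X, k, m = m, n_init = n_init, seed = seed)$objective
    }, numeric(1))
  )
}
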