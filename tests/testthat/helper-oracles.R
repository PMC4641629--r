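# Independent oracles, deliberately coded differently from the package:
# per-site loops and explicit normal equations instead of vectorized
# linear algebra, so agreement is evidence and not tautology.

# Textbook fuzzy c-means alternating optimization, one explicit start.
oracle_fcm <- function(X, k, m = 2, U0, max_iter = 500, tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X)
  U <- U0
  J_old <- Inf
  for (it in seq_len(max_iter)) {
    C <- matrix(0, k, ncol(X))
    for (h in seq_len(k)) {
      w <- U[, h]^m
      C[h, ] <- colSums(X * w) / sum(w)
    }
    D2 <- matrix(0, n, k)
    for (i in seq_len(n)) {
      for (h in seq_len(k)) D2[i, h] <- sum((X[i, ] - C[h, ])^2)
    }
    for (i in seq_len(n)) {
      if (any(D2[i, ] == 0)) {
        U[i, ] <- as.numeric(D2[i, ] == 0) / sum(D2[i, ] == 0)
      } else {
        for (h in seq_len(k)) {
          U[i, h] <- 1 / sum((D2[i, h] / D2[i, ])^(1 / (m - 1)))
        }
      }
    }
    J <- 0
    for (i in seq_len(n)) {
      for (h in seq_len(k)) J <- J + U[i, h]^m * D2[i, h]
    }
    if (is.finite(J_old) && abs(J_old - J) <= tol * max(J, 1e-300)) {
      J_old <- J
      break
    }
    J_old <- J
  }
  list(U = U, C = C, J = J_old)
}

# RDA by explicit normal equations plus a full eigendecomposition of the
# fitted covariance matrix.
oracle_rda <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X, center = TRUE, scale = TRUE)
  B <- solve(t(Xs) %*% Xs) %*% t(Xs) %*% Yc
  Yhat <- Xs %*% B
  ev <- eigen(t(Yhat) %*% Yhat / (n - 1), symmetric = TRUE)
  lambda <- ev$values[ev$values > max(ev$values) * 1e-10]
  list(
    B = B,
    eigenvalues = lambda,
    r2 = sum(Yhat^2) / sum(Yc^2),
    total_variance = sum(Yc^2) / (n - 1)
  )
}

# Sort-based percentile with linear interpolation between order statistics
# (p in [0, 1]); independent of stats::quantile.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Membership matrix columns reordered to best match a reference (truth) by
# greedy column correlation; used to align recovered clusters with ground
# truth before computing errors.
match_columns <- function(U, truth) {
  k <- ncol(U)
  perm <- integer(k)
  used <- logical(k)
  for (j in seq_len(k)) {
    cors <- vapply(seq_len(k), function(c2) {
      if (used[c2]) -Inf else stats::cor(truth[, j], U[, c2])
    }, numeric(1))
    perm[j] <- which.max(cors)
    used[perm[j]] <- TRUE
  }
  U[, perm, drop = FALSE]
}

# Small random scenario objects / matrices used across test files.
random_community <- function(n = 12, p = 6, seed = 1) {
  set.seed(seed)
  matrix(stats::rgamma(n * p, 2, 1), n, p,
         dimnames = list(sprintf("s%02d", 1:n), sprintf("t%02d", 1:p)))
}
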