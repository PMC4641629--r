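test_that("Hellinger transform matches its closed form and flags zero rows", {
  expect_equal(as.numeric(hellinger_transform(matrix(c(4, 0, 0), 1))),
               c(1, 0, 0))
  expect_equal(as.numeric(hellinger_transform(matrix(c(1, 1, 2), 1))),
               c(0.5, 0.5, sqrt(0.5)))
  # unit-sum rows reduce to the elementwise square root
  U <- matrix(c(0.2, 0.3, 0.5), 1)
  expect_equal(hellinger_transform(U), sqrt(U))
  # every transformed row has unit norm
  set.seed(4)
  M <- matrix(rgamma(40, 1), 8, 5)
  expect_equal(rowSums(hellinger_transform(M)^2), rep(1, 8))
  bad <- rbind(ok = c(1, 1), empty = c(0, 0))
  expect_error(hellinger_transform(bad), "empty")
  expect_error(hellinger_transform(matrix(-1)), "nonnegative")
})

test_that("adjusted R2 follows the Ezekiel correction", {
  expect_equal(adj_r2(1, 30, 5), 1)
  expect_equal(adj_r2(0.5, 10, 3), 0.25)
  expect_equal(adj_r2(0.1, 10, 8), -7.1)  # negative values are legitimate
  expect_error(adj_r2(0.5, 5, 4), "undefined")
})

test_that("RDA attains its exact limits", {
  set.seed(10)
  X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  B_true <- matrix(c(1, -0.5, 0.3, 0.8, -0.2, 0.1), 2, 3)
  Y <- X %*% B_true
  fit <- rda_fit(Y, X)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(sum(fit$residual_eigenvalues), 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  # orthogonal single predictor: R2 = 0
  Yc <- scale(Y, scale = FALSE)
  x_orth <- qr.resid(qr(cbind(1, Yc)), rnorm(15))
  fit0 <- rda_fit(Y, matrix(x_orth, dimnames = list(NULL, "z")))
  expect_lt(fit0$r2, 1e-10)
})

test_that("RDA rejects rank-deficient and constant predictors, warns when saturated", {
  set.seed(11)
  Y <- matrix(rnorm(30), 10, 3)
  X <- cbind(a = rnorm(10), b = rnorm(10))
  expect_error(rda_fit(Y, cbind(X, dup = X[, "a"])), "dup")
  expect_error(rda_fit(Y, cbind(X, flat = rep(2, 10))), "constant")
  Xbig <- matrix(rnorm(90), 10, 9)
  expect_warning(fit_sat <- rda_fit(Y, Xbig), "saturated")
  expect_true(is.na(fit_sat$adj_r2))  # Ezekiel correction undefined at p = n - 1
  expect_error(rda_fit(Y, cbind(Xbig, z = rnorm(10))), "more predictors")
})

test_that("RDA matches the brute-force oracle and vegan on random instances", {
  skip_if_not_installed("vegan")
  set.seed(123)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    p <- sample(2:4, 1)
    q <- sample(2:4, 1)
    Y <- matrix(rnorm(n * q), n, q)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    fit <- rda_fit(Y, X)
    ora <- oracle_rda(Y, X)
    expect_equal(fit$r2, ora$r2, tolerance = 1e-10)
    expect_equal(fit$eigenvalues, ora$eigenvalues, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(unname(fit$coefficients), unname(ora$B), tolerance = 1e-8)
    v <- vegan::rda(Y ~ ., data = as.data.frame(X))
    expect_equal(fit$r2, vegan::RsquareAdj(v)$r.squared, tolerance = 1e-10)
    expect_equal(fit$adj_r2, vegan::RsquareAdj(v)$adj.r.squared,
                 tolerance = 1e-10)
    expect_equal(unname(fit$eigenvalues), unname(v$CCA$eig),
                 tolerance = 1e-8)
    # conservation: constrained + residual eigenvalues = total variance
    expect_equal(sum(fit$eigenvalues) + sum(fit$residual_eigenvalues),
                 fit$total_variance, tolerance = 1e-10)
    expect_equal(sum(fit$eigenvalues) / fit$total_variance, fit$r2,
                 tolerance = 1e-10)
  }
})

test_that("R2 is invariant to affine predictor rescaling", {
  set.seed(14)
  Y <- matrix(rnorm(36), 12, 3)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  X2 <- X
  X2[, 1] <- 100 * X2[, 1] - 7
  f1 <- rda_fit(Y, X)
  f2 <- rda_fit(Y, X2)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
  # standardized coefficients are unchanged (scaling is absorbed)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("axis permutation tests hit their analytic limits", {
  set.seed(15)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  Y <- X %*% matrix(rnorm(6), 2, 3)  # exactly linear: minimum attainable p
  p <- permtest_axes(Y + rnorm(n * 3, 0, 1e-8), X, n_perm = 199, seed = 2)
  expect_equal(p[[1]], 1 / 200)
  # add-one smoothing lower bound holds for pure noise too
  p_noise <- permtest_axes(matrix(rnorm(n * 3), n, 3), X, n_perm = 99, seed = 3)
  expect_true(all(p_noise >= 1 / 100))
  expect_error(permtest_axes(Y, X, n_perm = 0), "n_perm")
})

test_that("forward selection recovers a single strong driver and respects collinearity", {
  set.seed(16)
  n <- 30
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("V", 1:10)))
  Y <- cbind(X[, 1] * 2, -X[, 1], X[, 1]) + matrix(rnorm(n * 3, 0, 0.3), n, 3)
  sel <- forward_select(Y, X, n_perm = 199, seed = 4)
  expect_equal(sel$selected, "V1")
  expect_true(sel$stopped_by %in% c("alpha", "adjr2"))
  # duplicated predictor: exactly one of the pair selected, with a warning
  # (a second driver keeps selection running past the duplicate)
  Y2 <- cbind(2 * X[, 1] + X[, 2], -X[, 1] + X[, 2], X[, 1] - 2 * X[, 2]) +
    matrix(rnorm(n * 3, 0, 0.8), n, 3)
  Xdup <- cbind(X[, 1, drop = FALSE], V1copy = X[, 1], X[, 2:4])
  expect_warning(
    sel_dup <- forward_select(Y2, Xdup, n_perm = 199, seed = 5),
    "collinear"
  )
  expect_equal(sum(sel_dup$selected %in% c("V1", "V1copy")), 1)
})

test_that("forward selection retains multiple independent drivers", {
  set.seed(2)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("V", 1:10)))
  Y <- cbind(2 * X[, 1] + X[, 2], -X[, 1] + X[, 2], X[, 1] - 2 * X[, 2]) +
    matrix(rnorm(n * 3, 0, 0.8), n, 3)
  sel <- forward_select(Y, X, n_perm = 199, seed = 2)
  expect_true(all(c("V1", "V2") %in% sel$selected))
  expect_true(all(diff(c(0, sel$adj_r2_path)) > 0))  # each step adds variance
})

test_that("two-step subset selection finds the true drivers plus depth", {
  set.seed(17)
  n <- 33
  surface <- matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("S", 1:5)))
  hydro <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("H", 1:3)))
  depth <- rnorm(n, 18, 4)
  Y <- cbind(surface[, 2] - hydro[, 1], surface[, 2] + hydro[, 1],
             0.5 * surface[, 2]) + matrix(rnorm(n * 3, 0, 0.25), n, 3)
  res <- two_step_subset_selection(Y, list(surface = surface, hydro = hydro),
                                   depth, n_perm = 199, seed = 6)
  expect_true("S2" %in% res$selection$surface$selected)
  expect_true("H1" %in% res$selection$hydro$selected)
  expect_true("Depth" %in% res$final$variables)
  expect_true(all(res$final$axis_p >= 1 / 200))
  # all-noise groups collapse to a depth-only model
  Ynoise <- matrix(rnorm(n * 3), n, 3)
  expect_warning(
    res0 <- two_step_subset_selection(
      Ynoise, list(surface = surface[, 1:2]), depth, n_perm = 99, seed = 7),
    "depth-only"
  )
  expect_equal(res0$final$variables, "Depth")
})

test_that("variation partitioning identities hold exactly and match vegan", {
  skip_if_not_installed("vegan")
  set.seed(18)
  n <- 25
  A <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a1", "a2")))
  B <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("b1", "b2")))
  C <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "c1"))
  Y <- A %*% matrix(c(1, 0.5, -1, 0.2, 0.3, 0), 2, 3) +
    C %*% matrix(c(0.5, -0.5, 1), 1, 3) + matrix(rnorm(n * 3, 0, 0.5), n, 3)
  pt <- variation_partition(Y, list(A = A, B = B, C = C))
  # subtraction identity by construction, for every single conditioning
  for (g in c("A", "B", "C")) {
    for (h in setdiff(c("A", "B", "C"), g)) {
      u <- partition_term(pt, paste(sort(c(g, h)), collapse = "+"))
      expect_equal(partition_term(pt, paste0(g, "|", h)),
                   u - partition_term(pt, h), tolerance = 1e-12)
    }
  }
  expect_equal(partition_term(pt, "Residuals"), 1 - partition_term(pt, "All"),
               tolerance = 1e-12)
  vp <- vegan::varpart(Y, A, B, C)
  # marginal adjusted R2 of each single group matches vegan's
  vg <- vp$part$fract$Adj.R.square[1:3]
  expect_equal(c(partition_term(pt, "A"), partition_term(pt, "B"),
                 partition_term(pt, "C")), vg, tolerance = 1e-10)
  # orthogonal groups: explained variance is exactly additive on the plain R2
  # scale, so the unadjusted conditional fraction equals the marginal one
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, 2:5]  # mean-zero
  A2 <- Q[, 1:2, drop = FALSE]; B2 <- Q[, 3:4, drop = FALSE]
  colnames(A2) <- c("a1", "a2"); colnames(B2) <- c("b1", "b2")
  Y2 <- A2 %*% matrix(rnorm(6), 2, 3) + B2 %*% matrix(rnorm(6), 2, 3)
  r2 <- function(X) rda_fit(Y2, X, scale_x = FALSE)$r2
  expect_equal(r2(cbind(A2, B2)) - r2(B2), r2(A2), tolerance = 1e-8)
  expect_equal(r2(cbind(A2, B2)) - r2(A2), r2(B2), tolerance = 1e-8)
})

test_that("partition tables reject bad group structures", {
  Y <- matrix(rnorm(30), 10, 3)
  g <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "g"))
  expect_error(variation_partition(Y, list(a = g)), "2-4 groups")
  expect_error(variation_partition(Y, list(g, g)), "named")
  big <- matrix(rnorm(100), 10, 10)
  expect_error(variation_partition(Y, list(a = big, b = g)), "saturated")
})
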