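test_that("separated duplicates get crisp memberships and exact centroids", {
  X <- matrix(c(0, 0, 10, 10), ncol = 1)
  fit <- fkm_fit(X, k = 2, n_init = 20, seed = 1, tol = 1e-12)
  cent <- sort(as.numeric(fit$centroids))
  expect_equal(cent, c(0, 10), tolerance = 1e-9)
  own <- apply(fit$memberships, 1, max)
  expect_equal(own, rep(1, 4), tolerance = 1e-9, ignore_attr = TRUE)
  # a point midway between the centroids splits its membership evenly
  X5 <- rbind(X, 5)
  fit5 <- fkm_fit(X5, k = 2, n_init = 20, seed = 1, tol = 1e-14)
  expect_equal(as.numeric(fit5$memberships[5, ]), c(0.5, 0.5),
               tolerance = 1e-6)
})

test_that("input with fewer than k distinct rows is rejected", {
  X <- matrix(c(1, 1, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  expect_error(fkm_fit(X, k = 3, n_init = 5), "distinct")
  expect_error(fkm_fit(matrix(rnorm(10), 5, 2), k = 2, m = 1), "fuzziness")
})

test_that("alternating optimization agrees with an independent oracle from shared starts", {
  set.seed(12)
  X <- matrix(rnorm(24), 12, 2)
  for (s in 1:5) {
    set.seed(100 + s)
    U0 <- matrix(runif(12 * 3), 12, 3)
    U0 <- U0 / rowSums(U0)
    mine <- fkm_fit(X, k = 3, init = U0, tol = 1e-12)
    ref <- oracle_fcm(X, k = 3, U0 = U0, tol = 1e-12)
    expect_equal(mine$objective, ref$J, tolerance = 1e-6)
    expect_equal(unname(mine$memberships), unname(ref$U), tolerance = 1e-4)
  }
})

test_that("memberships match e1071::cmeans at the converged solution", {
  skip_if_not_installed("e1071")
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  fit <- fkm_fit(X, k = 3, n_init = 50, seed = 7)
  cm <- e1071::cmeans(X, centers = fit$centroids, m = 2)
  expect_lt(max(abs(fit$memberships - cm$membership)), 1e-4)
})

test_that("objective is non-increasing, row-stochastic and monotone in restarts", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  fit <- fkm_fit(X, k = 3, n_init = 40, seed = 3)
  expect_true(all(diff(fit$objective_trace) <= 1e-10 * fit$objective_trace[1]))
  expect_equal(rowSums(fit$memberships), rep(1, 20), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
  # stored objective is consistent with the stored memberships and centroids
  D2 <- as.matrix(stats::dist(rbind(X, fit$centroids)))^2
  D2 <- D2[1:20, 21:23]
  expect_equal(fit$objective, sum(fit$memberships^2 * D2),
               tolerance = 1e-8)
  # best objective over restarts is monotone in n_init under the shared stream
  j10 <- fkm_fit(X, k = 3, n_init = 10, seed = 3)$objective
  j40 <- fit$objective
  expect_lte(j40, j10)
  expect_equal(min(fit$objective_by_init[1:10]), j10)
})

test_that("permuting input rows permutes memberships identically", {
  set.seed(6)
  X <- matrix(rnorm(30), 10, 3)
  perm <- sample(10)
  f1 <- fkm_fit(X, k = 2, n_init = 30, seed = 9, tol = 1e-12)
  f2 <- fkm_fit(X[perm, ], k = 2, n_init = 30, seed = 9, tol = 1e-12)
  U2 <- match_columns(f2$memberships, f1$memberships[perm, ])
  expect_equal(unname(U2), unname(f1$memberships[perm, ]), tolerance = 1e-6)
})

test_that("cluster alignment undoes arbitrary column permutations", {
  U <- reference_membership_matrix()
  labels <- reference_memberships()$typ
  aligned <- align_clusters(U, labels)
  expect_equal(attr(aligned, "permutation"), 1:3)  # printed table already optimal
  expect_equal(unname(aligned), unname(U), ignore_attr = TRUE)
  swapped <- U[, c(3, 1, 2)]
  realigned <- align_clusters(swapped, labels)
  expect_equal(unname(realigned), unname(U), ignore_attr = TRUE)
  expect_equal(colnames(realigned), c("FKM_A", "FKM_B", "FKM_C"))
  expect_error(align_clusters(U[, 1:2], labels), "distinct expert labels")
})

test_that("mismatch report flags disagreements and ties separately", {
  U <- matrix(c(0.8, 0.1, 0.1,
                0.1, 0.8, 0.1,
                0.4, 0.4, 0.2), 3, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("FKM_A", "FKM_B", "FKM_C")))
  rep1 <- mismatch_report(U, c("A", "A", "A"))
  expect_equal(rep1$mismatches, "s2")
  expect_equal(rep1$count, 1)
  expect_equal(rep1$ties, "s3")   # tied row is not a mismatch
  rep2 <- mismatch_report(U[1:2, ], c("A", "B"))
  expect_equal(rep2$count, 0)
  expect_length(rep2$mismatches, 0)
})

test_that("membership summaries handle crisp and maximally fuzzy cases", {
  crisp <- diag(3)[c(1, 1, 2, 3, 3, 3), ]
  colnames(crisp) <- paste0("FKM_", LETTERS[1:3])
  s <- membership_summary(crisp, threshold = 0.5)
  expect_equal(unname(s$counts), c(2, 1, 3))
  expect_equal(s$high_fuzziness, 0)
  uniform <- matrix(1 / 3, 4, 3)
  su <- membership_summary(uniform, threshold = 0.5)
  expect_equal(unname(su$counts), c(0, 0, 0))
  expect_equal(su$high_fuzziness, 4)
  expect_error(membership_summary(crisp, threshold = 1.2), "threshold")
})

test_that("clustering recovers well-separated fuzzy memberships at r > 0.9 per cluster", {
  # ground-truth memberships sampled near the simplex vertices: the
  # well-separated, low-fuzziness regime
  for (s in 1:3) {
    set.seed(s)
    n <- 33
    main <- sample(1:3, n, replace = TRUE)
    U <- matrix(runif(n * 3, 0.02, 0.15), n, 3)
    U[cbind(1:n, main)] <- runif(n, 0.6, 0.95)
    U <- U / rowSums(U)
    sc <- synthetic_scenario(seed = s, noise_sd = 0.15)
    sc$n_sites <- as.integer(n)
    comm <- generate_community(list(memberships = U), sc)
    fit <- fkm_fit(hellinger_transform(comm), k = 3, n_init = 60, seed = s)
    Um <- match_columns(fit$memberships, U)
    for (h in 1:3) {
      expect_gt(stats::cor(Um[, h], U[, h]), 0.9)
    }
    expect_lt(mean(abs(Um - U)), 0.15)
  }
})

test_that("clustering the default study design tracks the fuzzier geometric truth", {
  sc <- synthetic_scenario(seed = 1)
  st <- generate_stations(sc)
  comm <- generate_community(st$truth, sc)
  fit <- fkm_fit(hellinger_transform(comm), k = 3, n_init = 60, seed = 1)
  U <- match_columns(fit$memberships, st$truth$memberships)
  expect_lt(mean(abs(U - st$truth$memberships)), 0.15)
  expect_gt(min(diag(stats::cor(U, st$truth$memberships))), 0.85)
})

test_that("the k-profile diagnostic reports one objective per candidate k", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  prof <- fkm_k_profile(X, k_range = 2:4, n_init = 10, seed = 1)
  expect_equal(prof$k, 2:4)
  expect_true(all(diff(prof$objective) < 0))  # J decreases with k
})
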