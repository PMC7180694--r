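test_that("concentration levels are floor(ln c) remapped contiguously", {
  lv <- concentration_levels(100)
  expect_equal(attr(lv, "raw_levels"), 4L)   # floor(ln 100) = 4
  lv2 <- concentration_levels(exp(3))        # boundary on its own integer
  expect_equal(attr(lv2, "raw_levels"), 3L)
  lv3 <- concentration_levels(c(10, 100, 1000))
  expect_equal(attr(lv3, "raw_levels"), c(2L, 4L, 6L))
  expect_equal(as.integer(lv3), c(1L, 2L, 3L))
  expect_error(concentration_levels(c(10, -1)), "positive")
})

test_that("concentration-feature matrix follows the one-hot contract", {
  Y <- build_concentration_features(c(1L, 2L, 1L),
                                    labeled_mask = c(TRUE, TRUE, TRUE, FALSE),
                                    n = 4)
  expect_equal(unclass(Y)[1, ], c(1, 0, 1, 0), ignore_attr = TRUE)
  expect_equal(unclass(Y)[2, ], c(0, 1, 0, 0), ignore_attr = TRUE)

  Ky <- concentration_kernel(Y)
  expect_equal(Ky[1, 3], 1)   # same level
  expect_equal(Ky[1, 2], 0)   # different levels
  expect_true(all(Ky[, 4] == 0))  # unlabeled column

  # all samples unlabeled: zero coding and zero kernel
  Y0 <- build_concentration_features(integer(0), rep(FALSE, 3), 3)
  expect_true(all(Y0 == 0))
  expect_true(all(concentration_kernel(Y0) == 0))

  expect_error(build_concentration_features(c(1L, 5L), c(TRUE, TRUE), 2,
                                            n_levels = 3),
               "outside")
})

test_that("concentration kernel equals column inner products", {
  set.seed(11)
  lv <- sample(1:3, 5, replace = TRUE)
  Y <- build_concentration_features(lv, c(rep(TRUE, 5), FALSE), 6)
  Ky <- concentration_kernel(Y)
  Ym <- unclass(Y)
  for (i in 1:6) for (j in 1:6) {
    expect_identical(Ky[i, j], sum(Ym[, i] * Ym[, j]))
  }
})

test_that("with no concentration kernel the subspace is kernel PCA", {
  set.seed(12)
  Kx <- rand_psd(7)
  H <- centering_matrix(7)
  fit <- fit_micf(Kx, matrix(0, 7, 7), mu = 1, h = 3)
  ref <- eigen(Kx %*% H %*% Kx, symmetric = TRUE)$vectors[, 1:3]
  expect_lt(principal_angle(fit$W, ref), 1e-6)
})

test_that("the fitted transform is orthonormal with descending real eigenvalues", {
  for (seed in 1:5) {
    Kx <- rand_psd(6, seed = seed)
    set.seed(seed + 50)
    lv <- sample(1:2, 4, replace = TRUE)
    Ky <- concentration_kernel(
      build_concentration_features(lv, c(rep(TRUE, 4), FALSE, FALSE), 6))
    fit <- fit_micf(Kx, Ky, mu = 0.5, h = 3)
    expect_lt(max(abs(crossprod(fit$W) - diag(3))), 1e-8)
    expect_true(all(diff(fit$eigenvalues) <= 1e-9))
    expect_true(all(is.finite(fit$eigenvalues)))
  }
})

test_that("the eigen-solution beats random orthonormal maps on the objective", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    h <- sample(1:3, 1)
    Kx <- rand_psd(n)
    lv <- sample(1:2, n - 1, replace = TRUE)
    Ky <- concentration_kernel(
      build_concentration_features(lv, c(rep(TRUE, n - 1), FALSE), n))
    mu <- runif(1, 0.1, 2)
    fit <- fit_micf(Kx, Ky, mu = mu, h = h)
    best <- micf_objective(fit$W, Kx, Ky, mu)
    for (r in 1:200) {
      W <- rand_orthonormal(n, h)
      expect_gte(best - micf_objective(W, Kx, Ky, mu), -1e-9)
    }
  }
})

test_that("objective equals the retained eigenvalue sum and the naive product", {
  set.seed(14)
  Kx <- rand_psd(5)
  lv <- sample(1:2, 3, replace = TRUE)
  Ky <- concentration_kernel(
    build_concentration_features(lv, c(rep(TRUE, 3), FALSE, FALSE), 5))
  fit <- fit_micf(Kx, Ky, mu = 1.3, h = 2)
  obj <- micf_objective(fit$W, Kx, Ky, 1.3)
  expect_equal(obj, sum(fit$eigenvalues), tolerance = 1e-8)
  expect_lt(abs(obj - micf_objective_naive(fit$W, Kx, Ky, 1.3)), 1e-10)
  expect_error(micf_objective(matrix(1, 5, 2), Kx, Ky, 1), "orthonormal")
})

test_that("projection is W-transpose times the kernel", {
  Kx <- rand_psd(5, seed = 15)
  fit <- fit_micf(Kx, matrix(0, 5, 5), mu = 1, h = 5)
  # full-rank W: Z spans the same information; exact for W = I
  id_model <- structure(list(W = diag(5), mu = 1, h = 5L,
                             eigenvalues = rep(0, 5)),
                        class = "micf_model")
  expect_identical(micf_project(id_model, Kx), Kx)

  Kd <- Kx
  Kd[, 3] <- Kd[, 1]   # duplicated sample column
  Z <- micf_project(fit, Kd)
  expect_identical(Z[, 3], Z[, 1])
  expect_lt(max(abs(micf_project(fit, Kx) - t(fit$W) %*% Kx)), 1e-12)
  expect_error(micf_project(fit, rand_psd(4)), "dimension")
})

test_that("fitting is deterministic and validates its inputs", {
  Kx <- rand_psd(6, seed = 16)
  Ky <- rand_psd(6, seed = 17)
  f1 <- fit_micf(Kx, Ky, mu = 1, h = 2)
  f2 <- fit_micf(Kx, Ky, mu = 1, h = 2)
  expect_identical(f1$W, f2$W)
  expect_error(fit_micf(Kx, Ky, mu = 1, h = 7), "h <= n")
  expect_error(fit_micf(matrix(rnorm(36), 6, 6), Ky, 1, 2), "symmetric")
  expect_error(fit_micf(Kx, Ky, mu = -1, h = 2), "mu")
})

test_that("a large variance weight recovers the kernel-PCA subspace", {
  set.seed(18)
  X <- matrix(rnorm(64), 8, 8)
  Kx <- gram(X)
  lv <- sample(1:3, 6, replace = TRUE)
  Ky <- concentration_kernel(
    build_concentration_features(lv, c(rep(TRUE, 6), FALSE, FALSE), 8))
  H <- centering_matrix(8)
  ref <- eigen(Kx %*% H %*% Kx, symmetric = TRUE)$vectors[, 1:2]
  fit <- fit_micf(Kx, Ky, mu = 1e6, h = 2)
  expect_lt(principal_angle(fit$W, ref), 1e-3)
})
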