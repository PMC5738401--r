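test_that("hotelling_t2 matches the direct-formula oracle and squared t", {
  set.seed(11)
  for (rep in 1:10) {
    na <- sample(5:9, 1); nb <- sample(5:9, 1); m <- sample(1:3, 1)
    A <- matrix(rnorm(na * m), na, m)
    B <- matrix(rnorm(nb * m), nb, m) + 0.5
    ht <- hotelling_t2(A, B)
    # independently coded: pooled covariance route via stats::cov
    Sp <- ((na - 1) * cov(A) + (nb - 1) * cov(B)) / (na + nb - 2)
    d <- colMeans(A) - colMeans(B)
    T2_oracle <- as.numeric(na * nb / (na + nb) * t(d) %*% solve(Sp, d))
    expect_lt(abs(ht$T2 - T2_oracle), 1e-10 * max(1, T2_oracle))
    if (m == 1) {
      t_stat <- (mean(A) - mean(B)) /
        sqrt(Sp[1, 1] * (1 / na + 1 / nb))
      expect_lt(abs(ht$T2 - t_stat^2), 1e-10 * max(1, t_stat^2))
    }
  }
  # identical group means: T2 = 0, w = 0
  A <- matrix(c(1, -1, 0, 0, 0, 0, 1, -1), 4, 2)
  ht0 <- hotelling_t2(A, A)
  expect_equal(ht0$T2, 0)
  expect_equal(ht0$w, c(0, 0))
  expect_error(hotelling_t2(matrix(rnorm(4), 2), matrix(rnorm(4), 2)),
               "reduce m|too few")
})

test_that("parametric_p behaves as the F transform must", {
  expect_equal(parametric_p(0, 10, 10, 3), 1)
  ps <- sapply(c(0.5, 1, 2, 4, 8, 16), parametric_p, n_a = 10, n_b = 10, m = 3)
  expect_true(all(diff(ps) < 0))
  expect_error(parametric_p(1, 3, 2, 4), "degrees of freedom")
})

test_that("parametric null rejection rate is calibrated", {
  set.seed(12)
  m <- 3; n <- 15; reps <- 2000
  rej <- mean(replicate(reps, {
    A <- matrix(rnorm(n * m), n, m)
    B <- matrix(rnorm(n * m), n, m)
    ht <- hotelling_t2(A, B)
    parametric_p(ht$T2, n, n, m) < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("permutation p is exact under exhaustive enumeration", {
  set.seed(13)
  A <- matrix(rnorm(6), 3, 2) + 2
  B <- matrix(rnorm(6), 3, 2)
  pp <- permutation_p(A, B, B_perms = 100)
  expect_true(pp$exhaustive)
  expect_equal(pp$B, 20L)
  # independent enumeration oracle
  pooled <- rbind(A, B)
  t2s <- apply(combn(6, 3), 2, function(idx) {
    X <- pooled[idx, , drop = FALSE]; Y <- pooled[-idx, , drop = FALSE]
    d <- colMeans(X) - colMeans(Y)
    S <- crossprod(sweep(X, 2, colMeans(X))) +
      crossprod(sweep(Y, 2, colMeans(Y)))
    9 / 6 * 4 * as.numeric(t(d) %*% solve(S, d))
  })
  expect_equal(pp$p, mean(t2s >= pp$T2 - 1e-12 * pp$T2))
  # group-balanced duplication: observed T2 is 0, every permutation ties
  # or exceeds it, so p = 1
  A0 <- matrix(c(1, 2, 3), 3, 1)
  pd <- permutation_p(A0, A0, B_perms = 100)
  expect_equal(pd$p, 1)
})

test_that("permutation p hits the convention floor under full separation", {
  set.seed(14)
  A <- matrix(rnorm(30), 10, 3) + 50
  B <- matrix(rnorm(30), 10, 3)
  pp <- permutation_p(A, B, B_perms = 200, seed = 5)
  expect_false(pp$exhaustive)
  expect_equal(pp$p, 1 / 201)
  # determinism under the seed
  expect_identical(pp$p, permutation_p(A, B, B_perms = 200, seed = 5)$p)
})

test_that("discriminant back-projection respects the orthonormal basis", {
  set.seed(15)
  k <- 10; r <- 5
  E <- qr.Q(qr(matrix(rnorm(3 * k * r), 3 * k, r)))
  model <- structure(list(E = E, lambda = rep(1, r), k = k, m = 3),
                     class = "pca_model")
  w <- rnorm(3)
  md <- map_discriminant(w, model)
  expect_equal(dim(md$arrows), c(k, 3))
  expect_equal(as.numeric(crossprod(E, md$w_hat)), md$w_tilde,
               tolerance = 1e-12)
  expect_equal(md$w_tilde, c(w, 0, 0))
  # zero maps to zero
  expect_true(all(map_discriminant(rep(0, 3), model)$w_hat == 0))
  # identity basis, m = r: w_hat equals w
  idm <- structure(list(E = diag(6), lambda = rep(1, 6), k = 2, m = 6),
                   class = "pca_model")
  expect_equal(map_discriminant(1:6, idm)$w_hat, as.numeric(1:6))
  expect_error(map_discriminant(rnorm(r + 1), model), "more components")
})

test_that("levene battery: null calibration and dilation power", {
  set.seed(16)
  null_rej <- mean(replicate(1000, {
    A <- matrix(rnorm(15 * 2), 15, 2)
    B <- matrix(rnorm(15 * 2), 15, 2) + 3  # translated, same spread
    levene_tests(A, B, B_perms = 200, seed = 1)$mean < 0.05
  }))
  expect_lte(null_rej, 0.07)
  power <- mean(replicate(200, {
    A <- matrix(rnorm(50 * 2), 50, 2)
    B <- matrix(rnorm(50 * 2), 50, 2) * 3  # dilated 3x about its center
    levene_tests(A, B, B_perms = 200, seed = 1)$median < 0.01
  }))
  expect_gte(power, 0.95)
})

test_that("randomized levene variants are exact on tiny groups", {
  set.seed(17)
  A <- matrix(rnorm(6), 3, 2) * 3
  B <- matrix(rnorm(6), 3, 2)
  lv <- levene_tests(A, B, B_perms = 100, seed = 2)
  for (variant in c("mean", "median")) {
    cen <- function(M) if (variant == "mean") colMeans(M) else
      apply(M, 2, median)
    dev <- c(sqrt(rowSums(sweep(A, 2, cen(A))^2)),
             sqrt(rowSums(sweep(B, 2, cen(B))^2)))
    tstat <- function(da, db) {
      sp2 <- (sum((da - mean(da))^2) + sum((db - mean(db))^2)) / 4
      (mean(da) - mean(db)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    }
    tobs <- tstat(dev[1:3], dev[4:6])
    tp <- apply(combn(6, 3), 2, function(idx) tstat(dev[idx], dev[-idx]))
    expect_equal(lv[[paste0("randomized_", variant)]],
                 mean(abs(tp) >= abs(tobs) - 1e-12 * abs(tobs)))
  }
  # all-zero deviations
  Z <- matrix(rep(c(0, 0), each = 3), 3, 2)
  expect_warning(lz <- levene_tests(Z, Z, B_perms = 100), "zero")
  expect_equal(lz$mean, 1)
})

test_that("group mean shapes follow their defining identities", {
  set.seed(18)
  X <- matrix(rnorm(5 * 12), 5, 12)
  sm <- center_and_scale(X, groups = c("a", "b", "b", "b", "b"))
  expect_equal(group_mean_shape(sm, "a"),
               matrix(sm$X[1, ], 4, 3, byrow = TRUE))
  expect_error(group_mean_shape(sm, "c"), "empty group")
  # symmetric pair averages to the center
  v <- rnorm(12)
  c0 <- as.vector(t(matrix(rnorm(12), 4, 3)))
  sm2 <- structure(list(X = rbind(c0 + v, c0 - v), k = 4L,
                        groups = c("g", "g")), class = "shape_matrix")
  expect_equal(group_mean_shape(sm2, "g"), matrix(c0, 4, 3, byrow = TRUE))
  # whole-sample group mean equals the PCA mean vector
  sm$groups <- rep("all", 5)
  m <- fit_pca(sm)
  expect_equal(as.vector(t(group_mean_shape(sm, "all"))), m$mean,
               tolerance = 1e-12)
})

test_that("label swap negates w and leaves T2 and p-values unchanged", {
  set.seed(19)
  A <- matrix(rnorm(8 * 3), 8, 3) + 1
  B <- matrix(rnorm(7 * 3), 7, 3)
  h1 <- hotelling_t2(A, B); h2 <- hotelling_t2(B, A)
  expect_equal(h1$T2, h2$T2, tolerance = 1e-12)
  expect_equal(h1$w, -h2$w, tolerance = 1e-12)
  p1 <- permutation_p(A, B, B_perms = 200, seed = 3)
  p2 <- permutation_p(B, A, B_perms = 200, seed = 3)
  expect_equal(p1$p, p2$p)
  expect_equal(parametric_p(h1$T2, 8, 7, 3), parametric_p(h2$T2, 7, 8, 3))
})

test_that("permutation p is invariant to the printed prefactor", {
  set.seed(20)
  A <- matrix(rnorm(5 * 2), 5, 2) + 1
  B <- matrix(rnorm(6 * 2), 6, 2)
  ps <- permutation_p(A, B, B_perms = 150, seed = 8, prefactor = "standard")
  pp <- permutation_p(A, B, B_perms = 150, seed = 8, prefactor = "printed")
  expect_identical(ps$p, pp$p)
  # the printed prefactor simplifies to (n_a + n_b - 2)
  hs <- hotelling_t2(A, B, "standard"); hp <- hotelling_t2(A, B, "printed")
  expect_equal(hp$T2 / hs$T2, (5 + 6) / (5 * 6), tolerance = 1e-12)
})
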