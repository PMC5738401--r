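test_that("initialization is on-surface, consistent, and needs >= 2 shapes", {
  s <- mask_to_sdf(make_ball_volume(1, 0.1))
  cfg <- corr_config(k_target = 4L)
  ps <- initialize_particles(list(s, s, s), cfg)
  for (a in 1:3) {
    r <- sqrt(sum(ps$positions[[a]]^2))
    expect_lt(abs(r - 1), 0.15)  # on the digitized ball surface
    expect_identical(ps$positions[[a]], ps$positions[[1]])
  }
  expect_error(initialize_particles(list(s), cfg), "at least 2")
})

test_that("splitting doubles counts with shared offsets and stays local", {
  plane <- make_plane_sdf(h = 0.1, n = 41)
  cfg <- corr_config(k_target = 2L, seed = 7)
  ps <- initialize_particles(list(plane, plane), cfg)
  ps$positions <- rep(list(matrix(c(0, 0, 0), 1)), 2)  # flat-region anchor
  pert <- 0.05
  ps2 <- split_particles(ps, perturbation = pert)
  expect_equal(ps2$k, 2L)
  for (a in 1:2) {
    expect_equal(nrow(ps2$positions[[a]]), 2L)
    # child stays within 2 x perturbation of the parent on a flat region
    expect_lt(sqrt(sum((ps2$positions[[a]][2, ] -
                          ps2$positions[[a]][1, ])^2)), 2 * pert)
  }
  # identical offsets across shapes, and deterministic under the same seed
  expect_identical(ps2$positions[[1]], ps2$positions[[2]])
  ps3 <- split_particles(ps, perturbation = pert)
  expect_identical(ps3$positions, ps2$positions)
})

test_that("sampling gradient is symmetric and matches finite differences", {
  plane <- make_plane_sdf(h = 0.1, n = 41)
  mk_ps <- function(pts) {
    structure(list(positions = list(pts, pts), surfaces = list(plane, plane),
                   k = nrow(pts), cfg = corr_config(), diag = 4),
              class = "particle_system")
  }
  # two particles on the plane: equal and opposite along the separation
  two <- rbind(c(-0.3, 0, 0), c(0.3, 0, 0))
  g2 <- sampling_entropy_gradient(mk_ps(two), 1)$grad
  expect_equal(g2[1, ], -g2[2, ], tolerance = 1e-10)
  expect_lt(abs(g2[1, 2]) + abs(g2[1, 3]), 1e-10)
  # hexagonal ring: net gradient at the center vanishes by symmetry
  ang <- 2 * pi * (0:5) / 6
  hex <- rbind(c(0, 0, 0), cbind(0.5 * cos(ang), 0.5 * sin(ang), 0))
  gh <- sampling_entropy_gradient(mk_ps(hex), 1)$grad
  expect_lt(sqrt(sum(gh[1, ]^2)), 1e-10)
  # finite-difference oracle on 5 random planar configurations, fixed sigma
  set.seed(41)
  for (rep in 1:5) {
    pts <- cbind(matrix(runif(12, -1, 1), 6, 2), 0)
    sigma <- runif(6, 0.3, 0.6)
    terms <- shapecorr:::.parzen_terms(pts, sigma, Inf)
    fd <- fd_grad(function(x) shapecorr:::.parzen_terms(x, sigma, Inf)$value,
                  pts, eps = 1e-6)
    expect_rel_equal(terms$grad, fd, 1e-4)
  }
})

test_that("ensemble gradient: zero at identical configs, matches FD, alpha-monotone", {
  set.seed(5)
  X0 <- matrix(rnorm(12), 1, 12)[rep(1, 4), ]
  et0 <- shapecorr:::.ensemble_terms(X0, alpha = 0.1)
  expect_lt(max(abs(et0$grad)), 1e-9)
  # finite differences on a random n=3, k=4 system
  X <- matrix(rnorm(36), 3, 12)
  for (alpha in c(0.05, 0.5)) {
    et <- shapecorr:::.ensemble_terms(X, alpha)
    fd <- fd_grad(function(x) shapecorr:::.ensemble_terms(x, alpha)$value, X)
    expect_rel_equal(et$grad, fd, 1e-4)
  }
  # per-mode pull lambda-coefficient never grows when alpha doubles
  lam <- shapecorr:::.ensemble_terms(X, 0.1)$lambda
  coef <- function(a) sqrt(pmax(lam, 0) * 2) / ((lam + a) * 2)
  expect_true(all(coef(0.2) <= coef(0.1) + 1e-15))
})

test_that("optimizer satisfies its invariants on a small ensemble", {
  surfs <- replicate(3, mask_to_sdf(make_ball_volume(1, 0.125)),
                     simplify = FALSE)
  cfg <- corr_config(k_target = 16L, seed = 11)
  ps <- optimize_correspondence(surfs, cfg)
  expect_equal(ps$k, 16L)
  for (a in 1:3) {
    expect_equal(nrow(ps$positions[[a]]), 16L)
    resid <- abs(sdf_value(surfs[[a]], ps$positions[[a]]))
    expect_lt(max(resid), cfg$surface_tol_frac * 0.125 + 1e-12)
  }
  # accepted steps never increase the frozen-parameter objective
  expect_true(all(ps$meta$trace$q_after <=
                    ps$meta$trace$q_before + 1e-9 * abs(ps$meta$trace$q_before)))
  # reproducibility
  ps2 <- optimize_correspondence(surfs, cfg)
  expect_identical(ps$positions, ps2$positions)
})

test_that("converged particle systems scale with the data (equivariance)", {
  pop <- generate_population(small_spec(n_per_group = c(a = 2),
                                        seed = 3))
  cfg <- corr_config(k_target = 16L, seed = 2)
  surfs1 <- lapply(pop$volumes, mask_to_sdf)
  ps1 <- optimize_correspondence(surfs1, cfg)
  # same voxel grid declared at doubled spacing = the same shapes x 2
  vol2 <- lapply(pop$volumes, function(v) binary_volume(v$grid, v$spacing * 2))
  surfs2 <- lapply(vol2, mask_to_sdf)
  ps2 <- optimize_correspondence(surfs2, cfg)
  for (a in 1:2) {
    expect_rel_equal(ps2$positions[[a]], 2 * ps1$positions[[a]], 1e-3)
  }
})

test_that("planted radial deformation is captured by the correspondences", {
  # family: common base deformed by known per-specimen axis scalings (a
  # smooth radial deformation r(u) with known parameters); undoing it
  # analytically from the ground truth should collapse the across-shape
  # variance to < 10% of its raw value
  spec <- population_spec(n_per_group = c(a = 6), base_axes = c(4, 2.5, 1.5),
                          within_group_sd = c(0.10, 0.07, 0.05),
                          voxel_spacing = 0.4, seed = 8)
  pop <- generate_population(spec)
  surfs <- lapply(pop$volumes, mask_to_sdf)
  ps <- optimize_correspondence(surfs, corr_config(k_target = 32L, seed = 6))
  k <- ps$k
  base_r <- apply_effect(list(axes = spec$base_axes, exponent = 4),
                         shape_effect("none"))
  undeformed <- lapply(seq_along(surfs), function(a) {
    pts <- ps$positions[[a]]  # generator centers every shape at the origin
    r <- sqrt(rowSums(pts^2))
    u <- pts / r
    axes_a <- as.numeric(pop$truth[a, c("a1", "a2", "a3")])
    spec_r <- apply_effect(list(axes = axes_a, exponent = 4),
                           shape_effect("none"))
    u * as.vector(r * base_r(u) / spec_r(u))
  })
  var_of <- function(lst) {
    X <- t(vapply(lst, function(p) as.vector(t(p)), numeric(3 * k)))
    sum(apply(X, 2, var))
  }
  expect_lt(var_of(undeformed) / var_of(ps$positions), 0.10)
})
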