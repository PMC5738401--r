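test_that("binary_volume enforces its invariants", {
  g <- array(0L, c(5, 5, 5)); g[3, 3, 3] <- 1L
  expect_s3_class(binary_volume(g, 1), "binary_volume")
  expect_error(binary_volume(array(0L, c(5, 5, 5)), 1), "foreground")
  expect_error(binary_volume(array(1L, c(5, 5, 5)), 1), "background|boundary")
  gb <- array(0L, c(5, 5, 5)); gb[1, 3, 3] <- 1L
  expect_error(binary_volume(gb, 1), "boundary")
  g2 <- array(0, c(5, 5, 5)); g2[3, 3, 3] <- 0.7
  expect_error(binary_volume(g2, 1), "0/1")
  expect_error(binary_volume(g, c(1, -1, 1)), "positive")
})

test_that("signed distance field matches the ball oracle", {
  R <- 1; h <- 0.125
  v <- make_ball_volume(R, h)
  for (sig in c(0, h)) {
    s <- mask_to_sdf(v, sig)
    expect_lt(abs(sdf_value(s, c(0, 0, 0)) - (-R)), 1.5 * h)
    expect_true(any(s$phi < 0) && any(s$phi > 0))
  }
  # composed-EDT convention: foreground-adjacent background voxels carry
  # their center-to-center distance, in (0, sqrt(3) h]
  s0 <- mask_to_sdf(v, 0)
  fg <- v$grid == 1L
  shifted <- array(FALSE, dim(fg))
  shifted[-1, , ] <- shifted[-1, , ] | fg[-dim(fg)[1], , ]
  shifted[-dim(fg)[1], , ] <- shifted[-dim(fg)[1], , ] | fg[-1, , ]
  adj <- shifted & !fg
  expect_true(all(s0$phi[adj] > 0 & s0$phi[adj] <= sqrt(3) * h + 1e-12))
  # bitwise determinism
  expect_identical(mask_to_sdf(v)$phi, mask_to_sdf(v)$phi)
})

test_that("|grad phi| stays in the distance-fidelity band near the surface", {
  v <- make_ball_volume(1, 0.1)
  s <- mask_to_sdf(v)
  near <- which(abs(s$phi) <= 2 * 0.1, arr.ind = TRUE) - 1
  pts <- near * 0.1 + matrix(s$origin, nrow(near), 3, byrow = TRUE)
  gm <- sqrt(rowSums(sdf_gradient(s, pts)^2))
  expect_gt(min(gm), 0.8)
  expect_lt(max(gm), 1.2)
})

test_that("near-surface SDF error shrinks with resolution", {
  err <- sapply(c(0.2, 0.1), function(h) {
    s <- mask_to_sdf(make_ball_volume(1, h))
    band <- which(abs(s$phi) <= 2 * h, arr.ind = TRUE) - 1
    pts <- band * h + matrix(s$origin, nrow(band), 3, byrow = TRUE)
    max(abs(sdf_value(s, pts) - (sqrt(rowSums(pts^2)) - 1)))
  })
  expect_lt(err[2], err[1])
})

test_that("projection onto an analytic sphere satisfies its contract", {
  s <- make_sphere_sdf(R = 1, h = 0.1)
  tol <- 1e-3
  p <- project_to_surface(c(2, 0, 0), s, tol = tol)
  expect_lt(abs(sqrt(sum(p^2)) - 1), tol + 0.01)  # trilinear-level accuracy
  # fixed point: an on-surface point is returned unchanged
  x0 <- matrix(c(1, 0, 0), 1)
  expect_equal(project_to_surface(x0, s, tol = tol), x0,
               ignore_attr = TRUE)
  # idempotence: re-projection moves less than tol
  p2 <- project_to_surface(p, s, tol = tol)
  expect_lt(sqrt(sum((p2 - p)^2)), tol)
  # degenerate gradient at the exact center: nudge or error, never silent
  pc <- project_to_surface(c(0, 0, 0), s, tol = tol, strict = FALSE)
  expect_true(!attr(pc, "converged")[1] ||
                abs(sqrt(sum(pc^2)) - 1) < tol + 0.01)
  expect_error(project_to_surface(c(10, 10, 10) * 0 + c(0, 0, 0),
                                  s, tol = 1e-9, max_iter = 2L),
               "projection failed")
})

test_that("extracted mesh matches area, containment and topology oracles", {
  R <- 1; h <- R / 10
  s <- mask_to_sdf(make_ball_volume(R, h))
  mesh <- extract_mesh(s)
  expect_lt(abs(mesh_area(mesh) / (4 * pi * R^2) - 1), 0.05)
  expect_equal(mesh_euler(mesh), 2L)
  expect_lt(max(abs(sdf_value(s, mesh$vertices))), sqrt(3) * h)
  # no zero crossing is rejected at construction
  expect_error(implicit_surface(array(1, c(4, 4, 4)), 1), "zero crossing")
})

test_that("volume formats round-trip and reject missing spacing", {
  v <- generate_population(small_spec(n_per_group = c(a = 1)))$volumes[[1]]
  dir <- withr::local_tempdir()
  for (fmt in c("nrrd", "mhd")) {
    p <- file.path(dir, paste0("v.", fmt))
    write_volume(v, p)
    v2 <- read_volume(p)
    expect_identical(v2$grid, v$grid)
    expect_identical(v2$spacing, v$spacing)
    expect_identical(v2$origin, v$origin)
  }
  # ascii encoding, non-isotropic spacing propagated
  g <- array(0L, c(6, 5, 4)); g[3:4, 2:3, 2:3] <- 1L
  va <- binary_volume(g, c(0.5, 0.75, 1.25))
  pa <- file.path(dir, "aniso.nrrd")
  write_volume(va, pa, encoding = "ascii")
  va2 <- read_volume(pa)
  expect_identical(va2$grid, va$grid)
  expect_equal(va2$spacing, c(0.5, 0.75, 1.25))
  # spacing header is mandatory
  bad <- file.path(dir, "bad.nrrd")
  writeLines(c("NRRD0004", "type: unsigned char", "dimension: 3",
               "sizes: 2 2 2", "encoding: ascii", "",
               paste(rep("0", 8), collapse = " ")), bad)
  expect_error(read_volume(bad), "spacing")
  # non-binary values are thresholded with a warning
  soft <- file.path(dir, "soft.nrrd")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 3 3 3",
               "space directions: (1,0,0) (0,1,0) (0,0,1)",
               "encoding: ascii", "",
               paste(c(rep(0, 13), 0.9, rep(0, 13)), collapse = " ")), soft)
  expect_warning(vs <- read_volume(soft), "binariz")
  expect_equal(sum(vs$grid), 1L)
})

test_that("mesh formats round-trip", {
  s <- mask_to_sdf(make_ball_volume(1, 0.2))
  mesh <- extract_mesh(s)
  dir <- withr::local_tempdir()
  for (fmt in c("ply", "vtk")) {
    p <- file.path(dir, paste0("m.", fmt))
    write_mesh(mesh, p)
    m2 <- read_mesh(p)
    expect_equal(m2$faces, mesh$faces)
    expect_equal(m2$vertices, mesh$vertices, tolerance = 1e-6)
  }
})
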