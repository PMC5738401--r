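test_that("zero-variance null spec reproduces identical volumes", {
  spec <- population_spec(n_per_group = c(a = 3, b = 3),
                          base_axes = c(4, 2.5, 1.5), within_group_sd = 0,
                          voxel_spacing = 0.5, seed = 4)
  pop <- generate_population(spec)
  expect_length(pop$volumes, 6L)
  for (i in 2:6) expect_identical(pop$volumes[[i]]$grid, pop$volumes[[1]]$grid)
})

test_that("study-layout spec yields 36 aligned volumes and truth records", {
  spec <- population_spec(
    n_per_group = c(wildtype = 12, heterozygous = 18, homozygous = 6),
    base_axes = c(4, 2.5, 1.5), voxel_spacing = 0.5, seed = 2)
  pop <- generate_population(spec)
  expect_length(pop$volumes, 36L)
  expect_equal(nrow(pop$truth), 36L)
  expect_equal(as.vector(table(pop$truth$group)[unique(pop$truth$group)]),
               c(12L, 18L, 6L))
  # foreground is one 26-connected component, closed surface topology
  for (i in c(1, 13, 31)) {
    expect_equal(count_components(pop$volumes[[i]]), 1L)
    expect_equal(mesh_euler(extract_mesh(mask_to_sdf(pop$volumes[[i]]))), 2L)
  }
  # determinism
  pop2 <- generate_population(spec)
  expect_identical(pop$truth, pop2$truth)
  expect_identical(pop$volumes[[7]]$grid, pop2$volumes[[7]]$grid)
})

test_that("ellipsoid voxel volume matches the analytic value within 2%", {
  spec <- population_spec(n_per_group = c(a = 1), base_axes = c(8, 5, 3),
                          within_group_sd = 0, exponent = 2,
                          voxel_spacing = 0.25, seed = 1)
  v <- generate_population(spec)$volumes[[1]]
  expect_lt(abs(volume_measure(v) / (4 / 3 * pi * 8 * 5 * 3) - 1), 0.02)
})

test_that("voxelized volume converges to the analytic volume with spacing", {
  err <- sapply(c(0.5, 0.25), function(h) {
    spec <- population_spec(n_per_group = c(a = 1), base_axes = c(4, 2.5, 1.5),
                            within_group_sd = 0, exponent = 2,
                            voxel_spacing = h, seed = 1)
    v <- generate_population(spec)$volumes[[1]]
    abs(volume_measure(v) - 4 / 3 * pi * 4 * 2.5 * 1.5)
  })
  expect_lte(err[2], err[1] / 2)
})

test_that("apply_effect: identity at amplitude 0, peak displacement at center", {
  params <- list(axes = c(4, 2.5, 1.5), exponent = 4)
  u <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1),
             c(0, sin(pi / 4), cos(pi / 4)))
  r0 <- apply_effect(params, shape_effect("none"))(u)
  expect_identical(apply_effect(params, shape_effect("lateral_bump", 0))(u),
                   r0)
  rb <- apply_effect(params, shape_effect("lateral_bump", 0.7,
                                          extent = pi / 4))(u)
  # maximum displacement exactly at the bump center, zero outside the extent
  expect_equal(rb[1] - r0[1], 0.7)
  expect_equal(rb[2], r0[2])
  expect_equal(rb[3], r0[3])
  # at the extent boundary the displacement has fallen to zero (C1 profile)
  expect_lt(rb[4] - r0[4], 1e-12)
  # edge inflection displaces inward at +x
  ri <- apply_effect(params, shape_effect("edge_inflection", 0.5))(u)
  expect_equal(ri[2] - r0[2], -0.5)
  expect_equal(ri[1], r0[1])
})

test_that("amplitude 0 reproduces the null family exactly", {
  s0 <- small_spec(effect = "none", seed = 9)
  s1 <- small_spec(effect = "lateral_bump", amplitude = c(0, 0), seed = 9)
  p0 <- generate_population(s0)
  p1 <- generate_population(s1)
  for (i in seq_along(p0$volumes)) {
    expect_identical(p0$volumes[[i]]$grid, p1$volumes[[i]]$grid)
  }
})

test_that("errors: unknown effect, undersized grid names the specimen", {
  expect_error(shape_effect("dent"), "should be one of")
  expect_error(population_spec(c(a = 2), effect_name = "dent"),
               "should be one of")
  spec <- population_spec(n_per_group = c(a = 2), base_axes = c(4, 2.5, 1.5),
                          voxel_spacing = 0.5, grid_shape = 13, seed = 1)
  expect_error(generate_population(spec), "a_01")
})

test_that("effect_support flags the planted angular region", {
  pts <- rbind(c(0, 3, 0), c(3, 0, 0), c(0, -3, 0), c(0, 2.8, 0.3))
  pts <- sweep(pts, 2, -c(5, 5, 5))  # arbitrary translation cancels
  sup <- effect_support(pts, "lateral_bump", pi / 3)
  expect_equal(sup, c(TRUE, FALSE, FALSE, TRUE))
  expect_false(any(effect_support(pts, "none")))
})

test_that("population round-trips through disk with a manifest", {
  pop <- generate_population(small_spec(n_per_group = c(a = 2, b = 1)))
  dir <- withr::local_tempdir()
  mpath <- write_population(pop, dir)
  man <- read.csv(mpath)
  expect_equal(nrow(man), 3L)
  v <- read_volume(man$path[2])
  expect_identical(v$grid, pop$volumes[[2]]$grid)
  expect_equal(v$spacing, pop$volumes[[2]]$spacing)
})
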