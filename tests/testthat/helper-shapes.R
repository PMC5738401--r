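# fixtures built in code: digitized balls, analytic SDF grids, small
# populations, and a central-difference gradient checker

make_ball_volume <- function(R = 1, h = 0.1, n = 2 * ceiling(R / h) + 7) {
  ax <- ((0:(n - 1)) - (n - 1) / 2) * h
  g <- array(0L, c(n, n, n))
  cc <- as.matrix(expand.grid(ax, ax, ax))
  g[sqrt(rowSums(cc^2)) <= R] <- 1L
  binary_volume(g, h)
}

# implicit surface with exact analytic sphere signed distances at the nodes
make_sphere_sdf <- function(R = 1, h = 0.1, n = 2 * ceiling(2.2 * R / h) + 1) {
  ax <- ((0:(n - 1)) - (n - 1) / 2) * h
  cc <- as.matrix(expand.grid(ax, ax, ax))
  phi <- array(sqrt(rowSums(cc^2)) - R, c(n, n, n))
  implicit_surface(phi, h)
}

# implicit surface of the plane z = 0 (phi = z), for flat-region tests
make_plane_sdf <- function(h = 0.1, n = 41) {
  ax <- ((0:(n - 1)) - (n - 1) / 2) * h
  phi <- array(rep(ax, each = n * n), c(n, n, n))
  implicit_surface(phi, h)
}

# small fast population for pipeline-level tests
small_spec <- function(n_per_group = c(a = 4, b = 4), effect = "none",
                       amplitude = 0, seed = 1, ...) {
  population_spec(n_per_group = n_per_group, base_axes = c(4, 2.5, 1.5),
                  within_group_sd = 0.05, effect_name = effect,
                  effect_amplitude = amplitude, voxel_spacing = 0.5,
                  seed = seed, ...)
}

# central-difference gradient of a scalar function of a matrix argument
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)) /
                        max(max(abs(expected)), 1e-12), tol)
}
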