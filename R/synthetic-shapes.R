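#' Planted group-effect specification
#'
#' A localized, C1-smooth radial deformation of the base shape used to plant
#' known group differences: `"lateral_bump"` is an outward radial bump
#' centered on the +y (lateral) axis, `"edge_inflection"` an inward radial
#' deflection centered on the +x (posterior-edge) axis, `"none"` the
#' identity. The displacement profile is `amplitude * cos^2(pi/2 * psi /
#' extent)` for angular distance `psi <= extent` from the effect center, 0
#' outside, which is continuously differentiable at the support boundary.
#'
#' @param name one of `"none"`, `"lateral_bump"`, `"edge_inflection"`.
#' @param amplitude peak radial displacement, world units (may be negative).
#' @param extent angular half-width of the support, radians, in (0, pi].
#' @return an object of class `shape_effect`.
#' @export
shape_effect <- function(name = c("none", "lateral_bump", "edge_inflection"),
                         amplitude = 0, extent = pi / 3) {
  name <- match.arg(name)
  stopifnot(is.finite(amplitude), extent > 0, extent <= pi)
  structure(list(name = name, amplitude = amplitude, extent = extent,
                 center = effect_center_direction(name)),
            class = "shape_effect")
}

#' Unit world direction at which a named effect is centered
#' @param name effect name.
#' @return length-3 unit vector (or NA for `"none"`).
#' @export
effect_center_direction <- function(name) {
  switch(name,
    none = c(NA_real_, NA_real_, NA_real_),
    lateral_bump = c(0, 1, 0),
    edge_inflection = c(1, 0, 0),
    stop("unknown effect name: ", name)
  )
}

# smooth bump profile on angular distance psi, support [0, extent]
.bump_profile <- function(psi, extent) {
  ifelse(psi < extent, cos(pi / 2 * psi / extent)^2, 0)
}

#' Radius sampler of a (deformed) superellipsoid
#'
#' Returns a function mapping unit directions (n x 3) to surface radii of
#' the base superellipsoid with the effect's radial displacement applied.
#' The base family is a p-norm ellipsoid (`exponent` 2 gives a true
#' ellipsoid; the default 4 gives flat-ish faces and edge-like features
#' closer to a bone plate).
#'
#' @param surface_params list with `axes` (3 semi-axes, world units) and
#'   optional `exponent` (default 4).
#' @param effect a [shape_effect()].
#' @return function(u) -> radii; `u` an n x 3 matrix of unit directions.
#' @export
apply_effect <- function(surface_params, effect) {
  stopifnot(inherits(effect, "shape_effect"))
  axes <- surface_params$axes
  p <- surface_params$exponent %||% 4
  stopifnot(length(axes) == 3L, all(axes > 0), p >= 2)
  sgn <- switch(effect$name, none = 0, lateral_bump = 1, edge_inflection = -1)
  amp <- sgn * effect$amplitude
  center <- effect$center
  extent <- effect$extent
  function(u) {
    u <- rbind(u)
    r0 <- (rowSums(abs(sweep(u, 2, axes, "/"))^p))^(-1 / p)
    if (amp == 0) return(r0)
    cosang <- pmin(1, pmax(-1, u %*% center))
    r0 + amp * .bump_profile(acos(cosang), extent)
  }
}

#' Synthetic shape-population specification
#'
#' Defines a family of superellipsoid-based 3D segmentations with smooth
#' within-group variation (log-normal per-axis scaling) and an optional
#' planted per-group effect, emulating the statistical structure of a small
#' multi-group morphometric cohort.
#'
#' @param n_per_group named (or unnamed) positive integers per group.
#' @param base_axes three semi-axis lengths, world units.
#' @param within_group_sd per-axis SD of log axis lengths (recycled to 3).
#' @param effect_name effect planted in the population (see
#'   [shape_effect()]); applied with per-group amplitudes.
#' @param effect_amplitude numeric vector, one amplitude per group
#'   (recycled); 0 for unaffected (reference) groups.
#' @param effect_extent angular half-width of the effect support, radians.
#' @param amplitude_sd SD of per-specimen amplitude jitter within a group.
#' @param exponent superellipsoid p-norm exponent (2 = ellipsoid).
#' @param voxel_spacing isotropic world units per voxel.
#' @param grid_shape voxels per dimension (length 1 or 3); default sized to
#'   hold the largest nominal shape with >= 2 voxels margin.
#' @param rotation_sd SD (radians) of a small random rigid rotation per
#'   specimen; default 0 (off).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_per_group, base_axes = c(8, 5, 3),
                            within_group_sd = 0.03,
                            effect_name = "none", effect_amplitude = 0,
                            effect_extent = pi / 3, amplitude_sd = 0,
                            exponent = 4, voxel_spacing = 0.5,
                            grid_shape = NULL, rotation_sd = 0, seed = 1L) {
  n_per_group <- unlist(n_per_group)  # tolerate JSON-parsed named lists
  base_axes <- as.numeric(unlist(base_axes))
  stopifnot(all(n_per_group >= 1), length(base_axes) == 3L,
            all(base_axes > 0), voxel_spacing > 0, all(within_group_sd >= 0),
            effect_extent > 0, effect_extent <= pi, amplitude_sd >= 0,
            rotation_sd >= 0, exponent >= 2)
  effect_name <- match.arg(effect_name,
                           c("none", "lateral_bump", "edge_inflection"))
  ngroups <- length(n_per_group)
  if (is.null(names(n_per_group))) {
    names(n_per_group) <- paste0("group", seq_len(ngroups))
  }
  effect_amplitude <- rep_len(effect_amplitude, ngroups)
  within_group_sd <- rep_len(within_group_sd, 3L)
  if (is.null(grid_shape)) {
    # nominal maximal radius: +4 sd of axis noise, plus effect, plus margin
    rmax <- max(base_axes) * exp(4 * max(within_group_sd)) +
      max(abs(effect_amplitude)) + 4 * amplitude_sd
    half <- ceiling(rmax / voxel_spacing) + 3L
    grid_shape <- rep(2L * half + 1L, 3L)
  }
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  structure(list(n_per_group = n_per_group, base_axes = base_axes,
                 within_group_sd = within_group_sd,
                 effect_name = effect_name,
                 effect_amplitude = effect_amplitude,
                 effect_extent = effect_extent, amplitude_sd = amplitude_sd,
                 exponent = exponent, voxel_spacing = voxel_spacing,
                 grid_shape = grid_shape, rotation_sd = rotation_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# rotation matrix from axis-angle (Rodrigues)
.rotation_matrix <- function(axis, angle) {
  a <- axis / vnorm(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a synthetic shape population
#'
#' Draws per-specimen axis triplets (log-normal around the base axes) and
#' effect amplitudes, voxelizes each deformed superellipsoid by evaluating
#' the radial inside test at voxel centers, and returns the volumes with an
#' index-aligned ground-truth table. Deterministic given `spec$seed`.
#'
#' @param spec a [population_spec()].
#' @return list with `volumes` (list of [binary_volume()]), `truth`
#'   (data.frame: specimen, group, axes, amplitude, rotation angle) and
#'   `spec`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape
  h <- rep(spec$voxel_spacing, 3)
  origin <- -(d - 1) / 2 * h
  coords <- voxel_coords(d, h, origin)
  rr <- row_norms(coords)
  nz <- rr > 0
  uu <- coords[nz, , drop = FALSE] / rr[nz]

  half_extent <- min((d - 1) / 2 * h)
  volumes <- list()
  rows <- list()
  idx <- 0L
  for (g in seq_along(spec$n_per_group)) {
    gname <- names(spec$n_per_group)[g]
    for (i in seq_len(spec$n_per_group[g])) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", gname, i)
      axes_i <- spec$base_axes * exp(stats::rnorm(3, 0, spec$within_group_sd))
      amp_i <- spec$effect_amplitude[g] + stats::rnorm(1, 0, 1) *
        spec$amplitude_sd
      if (spec$effect_name == "none") amp_i <- 0
      rot_angle <- 0
      R <- diag(3)
      if (spec$rotation_sd > 0) {
        ax <- stats::rnorm(3)
        rot_angle <- stats::rnorm(1, 0, spec$rotation_sd)
        R <- .rotation_matrix(ax, rot_angle)
      }
      rmax_i <- max(axes_i) + max(0, abs(amp_i))
      if (rmax_i > half_extent - 2.5 * max(h)) {
        stop(sprintf(paste0("grid too small for specimen %s: nominal radius",
                            " %.3g exceeds usable half-extent %.3g"),
                     sid, rmax_i, half_extent - 2.5 * max(h)))
      }
      eff <- shape_effect(spec$effect_name, amplitude = amp_i,
                          extent = spec$effect_extent)
      radius_fn <- apply_effect(list(axes = axes_i, exponent = spec$exponent),
                                eff)
      # shape rotated by R: inside(x) = r(|R^T x|) test
      u_loc <- uu %*% R
      inside <- logical(nrow(coords))
      inside[nz] <- rr[nz] <= radius_fn(u_loc)
      inside[!nz] <- TRUE  # grid center is always inside
      volumes[[idx]] <- binary_volume(array(inside, d), h, origin)
      rows[[idx]] <- data.frame(specimen = sid, group = gname,
                                a1 = axes_i[1], a2 = axes_i[2],
                                a3 = axes_i[3], amplitude = amp_i,
                                rotation = rot_angle,
                                stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(volumes = volumes, truth = truth, spec = spec)
}

#' Membership of points in a planted effect's angular support
#'
#' @param points n x 3 world/shape coordinates (taken relative to their
#'   centroid).
#' @param effect_name,effect_extent the planted effect's name and angular
#'   half-width.
#' @return logical vector: angular distance from the effect center direction
#'   is at most `effect_extent`.
#' @export
effect_support <- function(points, effect_name, effect_extent = pi / 3) {
  center <- effect_center_direction(effect_name)
  if (anyNA(center)) return(rep(FALSE, nrow(rbind(points))))
  points <- rbind(points)
  rel <- sweep(points, 2, colMeans(points))
  u <- rel / pmax(row_norms(rel), 1e-12)
  ang <- acos(pmin(1, pmax(-1, u %*% center)))
  as.vector(ang <= effect_extent)
}

#' Write a generated population to disk with a CSV manifest
#'
#' @param pop result of [generate_population()].
#' @param dir output directory (created if missing).
#' @param format `"nrrd"` or `"mhd"`.
#' @return path of the manifest CSV, invisibly.
#' @export
write_population <- function(pop, dir, format = c("nrrd", "mhd")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(pop$volumes))
  for (i in seq_along(pop$volumes)) {
    paths[i] <- file.path(dir, paste0(pop$truth$specimen[i], ".", format))
    write_volume(pop$volumes[[i]], paths[i])
  }
  manifest <- cbind(pop$truth, path = paths, stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
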