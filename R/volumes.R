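#' Binary segmentation volume
#'
#' A voxelized segmentation of one specimen: a 3D array of 0/1 values on a
#' regular grid with world-unit spacing and origin. World coordinates follow
#' the cell-centered convention `world = origin + index * spacing` with
#' 0-based indices.
#'
#' @param grid 3D array of 0/1 (logical or numeric).
#' @param spacing positive spacing per axis (length 1 or 3, world units).
#' @param origin world coordinate of voxel (0,0,0); default centers the grid
#'   on the world origin.
#' @return an object of class `binary_volume`.
#' @export
binary_volume <- function(grid, spacing, origin = NULL) {
  stopifnot(length(dim(grid)) == 3L)
  if (!is.logical(grid) && !all(grid == 0 | grid == 1)) {
    stop("grid values must be exactly 0/1")
  }
  g <- array(as.integer(grid != 0), dim = dim(grid))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (is.null(origin)) origin <- -(dim(g) - 1) / 2 * spacing
  origin <- rep_len(as.numeric(origin), 3L)
  nfg <- sum(g)
  if (nfg == 0L) stop("volume has empty foreground")
  if (nfg == length(g)) stop("volume has empty background")
  if (.touches_boundary(g)) {
    stop("foreground touches the grid boundary; enlarge the grid")
  }
  structure(list(grid = g, spacing = spacing, origin = origin),
            class = "binary_volume")
}

.touches_boundary <- function(g) {
  d <- dim(g)
  sum(g[c(1, d[1]), , ]) + sum(g[, c(1, d[2]), ]) + sum(g[, , c(1, d[3])]) > 0
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s voxels, spacing (%s), %d foreground\n",
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              sum(x$grid)))
  invisible(x)
}

# world coordinates of all voxel centers (n_voxels x 3), column-major order
voxel_coords <- function(d, spacing, origin) {
  ax <- lapply(1:3, function(a) origin[a] + spacing[a] * (seq_len(d[a]) - 1))
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' Foreground centroid of a binary volume (world units)
#' @param v a `binary_volume`.
#' @return length-3 world coordinate.
#' @export
volume_centroid <- function(v) {
  idx <- which(v$grid == 1L, arr.ind = TRUE) - 1
  colMeans(idx) * v$spacing + v$origin
}

#' Physical foreground volume of a binary segmentation
#' @param v a `binary_volume`.
#' @return foreground voxel count times voxel volume.
#' @export
volume_measure <- function(v) sum(v$grid) * prod(v$spacing)

#' Number of 26-connected foreground components
#' @param v a `binary_volume`.
#' @return integer component count.
#' @export
count_components <- function(v) {
  .count_components26(as.integer(v$grid), dim(v$grid))
}
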