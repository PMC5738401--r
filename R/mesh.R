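#' Triangle mesh
#'
#' @param vertices n x 3 matrix of world coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3L, all(faces >= 1L),
            all(faces <= nrow(vertices)))
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Extract the zero level set of an implicit surface as a triangle mesh
#'
#' Marching tetrahedra on the Kuhn 6-tetrahedron cube subdivision. The
#' subdivision is translation-consistent across cube faces, so the mesh is
#' watertight by construction; triangle orientation is outward (toward
#' positive phi).
#'
#' @param s an `implicit_surface`.
#' @return a [triangle_mesh()] in world coordinates.
#' @export
extract_mesh <- function(s) {
  stopifnot(inherits(s, "implicit_surface"))
  res <- .march_tets(s$phi, dim(s$phi), s$spacing, s$origin)
  if (nrow(res$faces) == 0L) stop("phi has no zero crossing")
  triangle_mesh(res$vertices, res$faces)
}

#' Total surface area of a triangle mesh
#' @param mesh a `triangle_mesh`.
#' @return summed triangle areas (world units squared).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(row_norms(cr)) / 2
}

#' Euler characteristic V - E + F of a triangle mesh
#' @param mesh a `triangle_mesh`.
#' @return integer Euler characteristic (2 for a topological sphere).
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ne <- nrow(unique(e))
  nv <- length(unique(as.vector(f)))
  nv - ne + nrow(f)
}
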