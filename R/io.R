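#' Read a segmentation volume (NRRD or MetaImage)
#'
#' Supports NRRD (`.nrrd`, encodings `raw` and `ascii`/`text`) and MetaImage
#' (`.mhd` + raw data file). The spacing header is mandatory: a file without
#' per-axis spacing is rejected rather than silently assuming 1. Non-binary
#' grids are binarized at 0.5 with a warning.
#'
#' @param path file path; format chosen by extension.
#' @return a [binary_volume()].
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    nrrd = .read_nrrd(path),
    mhd = .read_mhd(path),
    stop("unsupported volume format: .", ext)
  )
  g <- parsed$grid
  if (!all(g %in% c(0, 1))) {
    warning("non-binary volume read; binarizing at threshold 0.5")
    g <- array(as.integer(g >= 0.5), dim(g))
  }
  binary_volume(g, parsed$spacing, parsed$origin)
}

#' Write a segmentation volume (NRRD or MetaImage)
#'
#' @param v a [binary_volume()].
#' @param path output path (`.nrrd` or `.mhd`).
#' @param encoding for NRRD: `"raw"` (little-endian uint8) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, encoding = c("raw", "ascii")) {
  stopifnot(inherits(v, "binary_volume"))
  encoding <- match.arg(encoding)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = .write_nrrd(v, path, encoding),
    mhd = .write_mhd(v, path),
    stop("unsupported volume format: .", ext)
  )
  invisible(path)
}

.write_nrrd <- function(v, path, encoding) {
  d <- dim(v$grid)
  hdr <- c(
    "NRRD0004",
    "# shapecorr binary segmentation",
    "type: unsigned char",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            v$spacing[1], v$spacing[2], v$spacing[3]),
    "kinds: domain domain domain",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            v$origin[1], v$origin[2], v$origin[3]),
    if (encoding == "raw") "endian: little",
    sprintf("encoding: %s", encoding)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("", con)
  if (encoding == "raw") {
    writeBin(as.raw(as.integer(v$grid)), con)
  } else {
    writeLines(paste(as.integer(v$grid), collapse = " "), con)
  }
}

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3) stop("expected a 3D NRRD")
  if (!is.null(fields[["space directions"]])) {
    m <- regmatches(fields[["space directions"]],
                    gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirs <- t(vapply(m, function(s) {
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
    }, numeric(3)))
    spacing <- row_norms(dirs)
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else {
    stop("NRRD header has no spacing information (space directions/spacings)")
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  }
  enc <- fields$encoding %||% "raw"
  n <- prod(sizes)
  type <- fields$type %||% "unsigned char"
  if (enc %in% c("ascii", "txt", "text")) {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else if (enc == "raw") {
    vals <- switch(type,
      "unsigned char" = , "uint8" = , "uchar" =
        as.numeric(readBin(con, "raw", n = n)),
      "double" = readBin(con, "double", n = n, size = 8, endian = "little"),
      "float" = readBin(con, "double", n = n, size = 4, endian = "little"),
      stop("unsupported NRRD type: ", type)
    )
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  if (length(vals) != n) stop("truncated NRRD data")
  list(grid = array(vals, sizes), spacing = spacing, origin = origin)
}

.write_mhd <- function(v, path) {
  d <- dim(v$grid)
  rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            v$spacing[1], v$spacing[2], v$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            v$origin[1], v$origin[2], v$origin[3]),
    "ElementType = MET_UCHAR",
    sprintf("ElementDataFile = %s", rawname)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(as.raw(as.integer(v$grid)), con)
}

.read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  fields <- stats::setNames(
    lapply(kv, function(x) if (length(x) >= 2) x[2] else ""),
    vapply(kv, function(x) tolower(trimws(x[1])), "")
  )
  sizes <- as.integer(strsplit(fields$dimsize, "\\s+")[[1]])
  if (is.null(fields$elementspacing)) {
    stop("MetaImage header has no ElementSpacing")
  }
  spacing <- as.numeric(strsplit(fields$elementspacing, "\\s+")[[1]])
  origin <- if (!is.null(fields$offset)) {
    as.numeric(strsplit(fields$offset, "\\s+")[[1]])
  } else c(0, 0, 0)
  datafile <- file.path(dirname(path), fields$elementdatafile)
  type <- toupper(fields$elementtype %||% "MET_UCHAR")
  n <- prod(sizes)
  con <- file(datafile, "rb")
  on.exit(close(con))
  vals <- switch(type,
    MET_UCHAR = as.numeric(readBin(con, "raw", n = n)),
    MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = "little"),
    stop("unsupported MetaImage type: ", type)
  )
  if (length(vals) != n) stop("truncated MetaImage data")
  list(grid = array(vals, sizes), spacing = spacing, origin = origin)
}

#' Read a triangle mesh (ASCII PLY or legacy VTK polydata)
#' @param path file path (`.ply` or `.vtk`).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = .read_ply(path),
    vtk = .read_vtk_polydata(path),
    stop("unsupported mesh format: .", ext)
  )
}

#' Write a triangle mesh (ASCII PLY or legacy VTK polydata)
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path (`.ply` or `.vtk`).
#' @param vectors optional n_vertices x 3 matrix written as VTK point-data
#'   vectors (ignored for PLY).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, vectors = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = .write_ply(mesh, path),
    vtk = .write_vtk_polydata(mesh$vertices, mesh$faces, path, vectors),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

.write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  lines <- c(hdr,
             sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
}

.read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  endh <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(endh + 1):(endh + nv)]
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"),
                             function(x) as.integer(x[2:4]) + 1L))
  triangle_mesh(v, f)
}

.write_vtk_polydata <- function(vertices, faces, path, vectors = NULL,
                                title = "shapecorr polydata") {
  nv <- nrow(vertices)
  lines <- c("# vtk DataFile Version 3.0", title, "ASCII", "DATASET POLYDATA",
             sprintf("POINTS %d double", nv),
             sprintf("%.9g %.9g %.9g",
                     vertices[, 1], vertices[, 2], vertices[, 3]))
  if (!is.null(faces) && nrow(faces) > 0) {
    lines <- c(lines,
               sprintf("POLYGONS %d %d", nrow(faces), 4L * nrow(faces)),
               sprintf("3 %d %d %d",
                       faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L))
  } else {
    lines <- c(lines,
               sprintf("VERTICES %d %d", nv, 2L * nv),
               sprintf("1 %d", seq_len(nv) - 1L))
  }
  if (!is.null(vectors)) {
    lines <- c(lines, sprintf("POINT_DATA %d", nv), "VECTORS arrows double",
               sprintf("%.9g %.9g %.9g",
                       vectors[, 1], vectors[, 2], vectors[, 3]))
  }
  writeLines(lines, path)
}

.read_vtk_polydata <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  keywords <- grep("^[A-Z]", lines)
  pend <- c(keywords[keywords > ip], length(lines) + 1L)[1] - 1L
  toks <- as.numeric(unlist(strsplit(
    paste(lines[(ip + 1):pend], collapse = " "), "\\s+")))
  v <- matrix(toks[1:(3 * nv)], ncol = 3, byrow = TRUE)
  ipoly <- grep("^POLYGONS", lines)[1]
  if (is.na(ipoly)) stop("VTK polydata has no POLYGONS")
  npoly <- as.integer(strsplit(lines[ipoly], "\\s+")[[1]][2])
  fl <- lines[(ipoly + 1):(ipoly + npoly)]
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"),
                             function(x) as.integer(x[2:4]) + 1L))
  triangle_mesh(v, f)
}

# point-list serialization for particle systems: "x y z" per line,
# line number = correspondence index
write_points <- function(pts, path) {
  writeLines(sprintf("%.12g %.12g %.12g", pts[, 1], pts[, 2], pts[, 3]), path)
  invisible(path)
}

read_points <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  dimnames(m) <- NULL
  m
}
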