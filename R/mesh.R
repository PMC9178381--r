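# Triangle meshes: the `trimesh` class and Wavefront OBJ I/O.
#
# Internally faces are stored 1-based (R convention); the OBJ format is
# 1-based on disk and the patch JSON interchange format is 0-based on disk.
# Conversion happens only at the read/write boundary.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return object of class `trimesh`.
#' @export
#' @examples
#' trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  m <- structure(list(vertices = vertices, faces = faces), class = "trimesh")
  validate_trimesh(m)
  m
}

validate_trimesh <- function(m) {
  v <- m$vertices; f <- m$faces
  if (ncol(v) != 3L) stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (!all(is.finite(v))) stop("vertex coordinates must be finite", call. = FALSE)
  if (nrow(f) > 0) {
    if (ncol(f) != 3L) stop("faces must be an m x 3 matrix of vertex indices",
                            call. = FALSE)
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range [1, ", nrow(v), "]", call. = FALSE)
    degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(degen))
      stop("degenerate face(s) with repeated vertices: ",
           paste(which(degen)[seq_len(min(5, sum(degen)))], collapse = ", "),
           call. = FALSE)
  }
  invisible(m)
}

#' @export
print.trimesh <- function(x, ...) {
  cat("trimesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Read a triangles-only Wavefront OBJ file
#'
#' Parses `v` and `f` records; texture/normal sub-indices (`f v/vt/vn`) are
#' accepted and stripped. Any face with more or fewer than three vertices is
#' an error (meshes must be triangulated upstream; nothing is silently
#' re-triangulated).
#'
#' @param path path to an .obj file.
#' @return a [trimesh()].
#' @export
read_obj_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop("no vertices in OBJ file: ", path, call. = FALSE)
  vparts <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  nv <- lengths(vparts)
  if (any(nv < 3L)) stop("malformed vertex line in ", path, call. = FALSE)
  vertices <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  if (anyNA(vertices)) stop("non-numeric vertex coordinate in ", path, call. = FALSE)
  faces <- matrix(integer(0), 0, 3)
  if (length(flines) > 0) {
    fparts <- strsplit(sub("^f\\s+", "", flines), "\\s+")
    nvf <- lengths(fparts)
    if (any(nvf != 3L)) {
      bad <- which(nvf != 3L)[1]
      stop("face ", bad, " has ", nvf[bad],
           " vertices; only triangular faces are supported", call. = FALSE)
    }
    idx <- vapply(fparts, function(p)
      as.integer(sub("/.*$", "", p)), integer(3))
    faces <- t(idx)  # OBJ is 1-based, as is R
    if (anyNA(faces)) stop("malformed face line in ", path, call. = FALSE)
  }
  trimesh(vertices, faces)
}

#' Write a triangle mesh as Wavefront OBJ
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj_mesh <- function(mesh, path) {
  validate_trimesh(mesh)
  v <- mesh$vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(mesh$faces) > 0) {
    f <- mesh$faces
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

# Per-face areas (mm^2) and centroids of a subset of faces.
face_areas <- function(mesh, face_idx = seq_len(nrow(mesh$faces))) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  cc <- mesh$vertices[f[, 3], , drop = FALSE]
  ab <- b - a; ac <- cc - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

face_centroids <- function(mesh, face_idx = seq_len(nrow(mesh$faces))) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  (mesh$vertices[f[, 1], , drop = FALSE] +
     mesh$vertices[f[, 2], , drop = FALSE] +
     mesh$vertices[f[, 3], , drop = FALSE]) / 3
}
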