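# Articular surface patches: named subsets of mesh faces, with an optional
# reference direction used only to resolve the sign of fitted axes/normals.

#' Construct a surface patch
#'
#' @param name patch role label (e.g. `"femoral_head"`, `"femoral_condyles"`,
#'   `"acetabulum_R"`, `"sacral_centra"`, `"crus_proximal"`, `"crus_distal"`,
#'   `"pes_proximal"`, `"pes_distal_medial"`, `"pes_distal_lateral"`).
#' @param face_indices integer vector of 1-based face indices into `mesh`.
#' @param mesh the [trimesh()] the indices refer to.
#' @param reference_direction optional 3-vector; stored unit-normalized.
#'   Used by the primitive fitters to disambiguate the sign of a fitted axis
#'   or normal (e.g. "axis positive laterally"); never used for geometry.
#' @return object of class `surface_patch`.
#' @export
surface_patch <- function(name, face_indices, mesh,
                          reference_direction = NULL) {
  face_indices <- sort(unique(as.integer(face_indices)))
  if (length(face_indices) == 0L)
    stop("patch '", name, "' is empty", call. = FALSE)
  if (min(face_indices) < 1L || max(face_indices) > nrow(mesh$faces))
    stop("patch '", name, "' has face indices outside [1, ",
         nrow(mesh$faces), "]", call. = FALSE)
  if (!is.null(reference_direction)) {
    reference_direction <- unit3(as.numeric(reference_direction))
  }
  structure(list(name = name, face_indices = face_indices,
                 reference_direction = reference_direction),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat("surface_patch '", x$name, "': ", length(x$face_indices), " faces",
      if (!is.null(x$reference_direction)) " (+reference direction)", "\n",
      sep = "")
  invisible(x)
}

#' Unique vertex coordinates of a patch
#'
#' @param patch a [surface_patch()].
#' @param mesh the mesh it indexes.
#' @return numeric matrix, k x 3.
#' @export
patch_vertices <- function(patch, mesh) {
  vidx <- sort(unique(as.vector(mesh$faces[patch$face_indices, , drop = FALSE])))
  mesh$vertices[vidx, , drop = FALSE]
}

#' Total surface area of a patch (mm^2)
#' @inheritParams patch_vertices
#' @return scalar area.
#' @export
patch_area <- function(patch, mesh) sum(face_areas(mesh, patch$face_indices))

# Patch roles the pipeline knows how to consume. Anything else in a patch
# file is rejected so that typos surface early.
known_patch_roles <- function() {
  c("acetabulum_R", "acetabulum_L", "sacral_centra",
    "femoral_head", "femoral_condyles",
    "crus_proximal", "crus_distal",
    "pes_proximal", "pes_distal", "pes_distal_medial", "pes_distal_lateral")
}

#' Read a patch-selection JSON file
#'
#' The on-disk schema maps patch role names to either a bare array of face
#' indices or an object `{"faces": [...], "reference_direction": [x,y,z]}`.
#' File indices are 0-based (the interchange convention); they are converted
#' to this package's 1-based indices on read.
#'
#' @param path path to a JSON file.
#' @param mesh the [trimesh()] the patches index; used for validation.
#' @param roles optional character vector of accepted role names; defaults to
#'   [known_patch_roles()].
#' @return named list of [surface_patch()] objects.
#' @export
read_patches <- function(path, mesh, roles = known_patch_roles()) {
  if (!file.exists(path)) stop("patch file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)))
    stop("patch file must be a JSON object mapping role names to selections",
         call. = FALSE)
  out <- list()
  for (nm in names(raw)) {
    if (!nm %in% roles)
      stop("unknown patch role '", nm, "' (known: ",
           paste(roles, collapse = ", "), ")", call. = FALSE)
    entry <- raw[[nm]]
    if (is.list(entry) || !is.null(names(entry))) {
      faces0 <- entry[["faces"]]
      refdir <- entry[["reference_direction"]]
    } else {
      faces0 <- entry
      refdir <- NULL
    }
    faces0 <- as.integer(faces0)
    if (any(faces0 < 0L) || any(faces0 > nrow(mesh$faces) - 1L))
      stop("patch '", nm, "': face index out of range [0, ",
           nrow(mesh$faces) - 1L, "]", call. = FALSE)
    out[[nm]] <- surface_patch(nm, faces0 + 1L, mesh,
                               reference_direction = refdir)
  }
  out
}

#' Write patches to the JSON interchange format (0-based indices)
#'
#' @param patches named list of [surface_patch()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patches <- function(patches, path) {
  obj <- lapply(patches, function(p) {
    entry <- list(faces = p$face_indices - 1L)
    if (!is.null(p$reference_direction))
      entry$reference_direction <- p$reference_direction
    entry
  })
  names(obj) <- vapply(patches, `[[`, "", "name")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
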