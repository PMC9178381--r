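# From meshes + patch selections to fitted primitives and ACS sets: the
# glue between the fitting module and the coordinate-system builders.

# Primitive type expected for each patch role.
patch_primitive_type <- function(role) {
  switch(role,
         acetabulum_R = , acetabulum_L = , femoral_head = "sphere",
         sacral_centra = , femoral_condyles = , crus_distal = ,
         pes_distal = , pes_distal_medial = , pes_distal_lateral = "cylinder",
         crus_proximal = , pes_proximal = "plane",
         stop("no primitive type known for patch role '", role, "'",
              call. = FALSE))
}

#' Fit the appropriate primitive to every patch of a segment
#'
#' Patch roles determine the primitive: spheres for acetabula and femoral
#' head, cylinders for sacral centra and all condylar/roller patches, planes
#' for proximal articular surfaces. Axis/normal signs are resolved by each
#' patch's reference direction.
#'
#' @param mesh a [trimesh()].
#' @param patches named list of [surface_patch()]es on `mesh`.
#' @return named list of fit objects ([fit_sphere()], [fit_cylinder()],
#'   [fit_plane()] results).
#' @export
fit_segment_patches <- function(mesh, patches) {
  fits <- lapply(patches, function(p) {
    switch(patch_primitive_type(p$name),
           sphere = fit_sphere(p, mesh),
           cylinder = fit_cylinder(p, mesh),
           plane = fit_plane(p, mesh))
  })
  names(fits) <- names(patches)
  fits
}

#' Fit primitives for every segment of a limb
#'
#' @param limb a [generate_limb()] result, or any list with a `segments`
#'   element of the same shape (each segment: `mesh`, `patches`).
#' @return named list (per segment) of named fit lists.
#' @export
fit_limb_primitives <- function(limb) {
  lapply(limb$segments, function(seg)
    fit_segment_patches(seg$mesh, seg$patches))
}

#' Build the full ACS set from fitted primitives
#'
#' @param fits per-segment fit lists from [fit_limb_primitives()].
#' @param sides which sides to build (`"right"`, `"left"`).
#' @return flat named ACS set usable with [assemble_reference_pose()],
#'   [limb_jcs()] and [limb_pose_table()].
#' @export
fitted_acs_set <- function(fits, sides = "right") {
  sides <- match.arg(sides, c("right", "left"), several.ok = TRUE)
  pel <- fits$pelvis
  acs_set <- build_pelvic_acs(pel$acetabulum_R, pel$acetabulum_L,
                              pel$sacral_centra)
  for (side in sides) {
    sfx <- side_suffix(side)
    fem <- fits[[paste0("femur_", side)]]
    fa <- build_femoral_acs(fem$femoral_head, fem$femoral_condyles, side)
    cru <- fits[[paste0("crus_", side)]]
    ca <- build_crural_acs(cru$crus_proximal, cru$crus_distal, side)
    pes <- fits[[paste0("pes_", side)]]
    pa <- build_pedal_acs_static(pes$pes_proximal, pes$pes_distal, side)
    acs_set[[paste0("hipACSm", sfx)]] <- fa$hipACSm
    acs_set[[paste0("kneeACSf", sfx)]] <- fa$kneeACSf
    acs_set[[paste0("kneeACSm", sfx)]] <- ca$kneeACSm
    acs_set[[paste0("ankleACSf", sfx)]] <- ca$ankleACSf
    acs_set[[paste0("ankleACSm", sfx)]] <- pa
  }
  acs_set
}

#' Orthonormality and anatomical-direction report for an ACS set
#'
#' Every ACS is checked for orthonormality and right-handedness; where the
#' proxies list declares expected anatomical directions, the signed
#' agreement of each axis with its proxy is reported.
#'
#' @param acs_set flat named ACS set.
#' @param expectations optional named list: per ACS-set entry, a named list
#'   mapping axis to proxy direction (see [acs_direction_report()]).
#' @return data.frame; one row per check.
#' @export
acs_set_report <- function(acs_set, expectations = NULL) {
  rows <- lapply(names(acs_set), function(nm) {
    a <- acs_set[[nm]]
    ortho <- max(abs(crossprod(a$axes) - diag(3)))
    handed <- det(a$axes)
    base <- data.frame(acs = nm, side = a$side, axis = "(triad)",
                       dot = NA_real_, ok = ortho < ACS_ORTHO_TOL &
                         abs(handed - 1) < ACS_ORTHO_TOL)
    if (!is.null(expectations[[nm]]))
      base <- rbind(base, acs_direction_report(a, expectations[[nm]]))
    base
  })
  do.call(rbind, rows)
}
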