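# Anatomical coordinate systems (ACS): an origin plus a right-handed
# orthonormal triad rigidly attached to a segment, derived from fitted
# articular primitives via each segment's T-shaped principal vectors
# (an intercentroid long axis plus a transverse axis, not necessarily
# perpendicular: orthogonality enters only through cross products).
#
# The constructions are deliberately left/right asymmetric so that
# equivalent anatomical motions are measured with equal sign in both limbs.

ACS_ORTHO_TOL <- 1e-9

# Guard against a degenerate "T": long and transverse axes closer than 5
# degrees make the cross products numerically unstable.
T_PARALLEL_GUARD_DEG <- 5

#' Construct an anatomical coordinate system
#'
#' @param name ACS label (e.g. `"hipACSm"`).
#' @param side `"right"`, `"left"`, `"midline"` (pelvis), or `"ground"`.
#' @param origin 3-vector (mm).
#' @param X,Y,Z unit 3-vectors forming a right-handed orthonormal triad.
#' @return object of class `acs`; axes stored as the columns of `$axes`.
#' @export
acs <- function(name, side, origin, X, Y, Z) {
  side <- match.arg(side, c("right", "left", "midline", "ground"))
  axes <- cbind(X = as.numeric(X), Y = as.numeric(Y), Z = as.numeric(Z))
  a <- structure(list(name = name, side = side,
                      origin = as.numeric(origin), axes = axes),
                 class = "acs")
  validate_acs(a)
  a
}

validate_acs <- function(a, tol = ACS_ORTHO_TOL) {
  A <- a$axes
  if (!all(is.finite(A)) || !all(is.finite(a$origin)))
    stop("ACS '", a$name, "': non-finite origin or axes", call. = FALSE)
  if (max(abs(crossprod(A) - diag(3))) > tol)
    stop("ACS '", a$name, "': axes are not orthonormal within ", tol,
         call. = FALSE)
  if (abs(det(A) - 1) > tol)
    stop("ACS '", a$name, "': axes are not right-handed (det != +1)",
         call. = FALSE)
  invisible(a)
}

#' @export
print.acs <- function(x, ...) {
  cat(sprintf("acs %s (%s): origin (%.3f, %.3f, %.3f) mm\n",
              x$name, x$side, x$origin[1], x$origin[2], x$origin[3]))
  ax <- t(x$axes)
  dimnames(ax) <- list(c("X", "Y", "Z"), NULL)
  print(round(ax, 6))
  invisible(x)
}

acs_axis <- function(a, which) a$axes[, which]

#' Express an ACS in world coordinates
#'
#' @param a an [acs()] defined in segment-local coordinates.
#' @param tf the segment's [rigid_transform()] (local -> world).
#' @return an [acs()] with world origin and axes.
#' @export
acs_world <- function(a, tf) {
  acs(a$name, a$side,
      apply_transform(tf, a$origin),
      as.vector(tf$R %*% a$axes[, "X"]),
      as.vector(tf$R %*% a$axes[, "Y"]),
      as.vector(tf$R %*% a$axes[, "Z"]))
}

check_t_parallel <- function(long_axis, transverse, what) {
  ang <- line_angle(long_axis, transverse) * RAD2DEG
  if (ang < T_PARALLEL_GUARD_DEG)
    stop(what, ": long and transverse principal vectors are within ",
         T_PARALLEL_GUARD_DEG, " degrees of parallel (", round(ang, 2),
         " deg)", call. = FALSE)
  invisible(ang)
}

#' Build the pelvic ACSs from acetabular spheres and the sacral cylinder
#'
#' Produces three coordinate systems attached to the pelvis:
#' * `pelvicACSm` — origin midway between the acetabular sphere centroids;
#'   Y from left toward right acetabulum, Z = Y x sacral axis (dorsal),
#'   X = Y x Z (caudal).
#' * `hipACSf_R`, `hipACSf_L` — origins at the respective acetabular
#'   centroids; Z from right toward left centroid on both sides; Y =
#'   Z x sacral axis on the right (ventral) but sacral axis x Z on the left
#'   (dorsal); X = Y x Z (right cranial, left caudal).
#'
#' @param acet_R,acet_L [fit_sphere()] results for the right and left
#'   acetabular patches.
#' @param sacral [fit_cylinder()] result for the sacral centra, axis already
#'   sign-resolved positive cranially.
#' @return named list `pelvicACSm`, `hipACSf_R`, `hipACSf_L`.
#' @export
build_pelvic_acs <- function(acet_R, acet_L, sacral) {
  oR <- acet_R$centroid
  oL <- acet_L$centroid
  if (vnorm(oR - oL) < 1e-12)
    stop("acetabular centroids coincide", call. = FALSE)
  s <- unit3(sacral$axis)
  Ym <- unit3(oR - oL)                     # positive to the right
  check_t_parallel(Ym, s, "pelvicACSm")
  Zm <- unit3(cross3(Ym, s))               # positive dorsally
  Xm <- cross3(Ym, Zm)                     # positive caudally
  pelvic <- acs("pelvicACSm", "midline", (oR + oL) / 2, Xm, Ym, Zm)

  Z <- unit3(oL - oR)                      # both sides positive to the left
  YR <- unit3(cross3(Z, s))                # right: positive ventrally
  XR <- cross3(YR, Z)                      # right: positive cranially
  YL <- unit3(cross3(s, Z))                # left: positive dorsally
  XL <- cross3(YL, Z)                      # left: positive caudally
  list(pelvicACSm = pelvic,
       hipACSf_R = acs("hipACSf", "right", oR, XR, YR, Z),
       hipACSf_L = acs("hipACSf", "left", oL, XL, YL, Z))
}

#' Build the femoral ACSs from the head sphere and condylar cylinder
#'
#' `hipACSm` sits at the head-sphere centroid, `kneeACSf` at the condylar
#' cylinder centroid. On the right, `hipACSm_X` runs from head to condyles
#' (positive distally); on the left the subtraction is reversed (positive
#' proximally). The condylar axis (sign-resolved right-lateral /
#' left-medial) is `kneeACSf_Z`. A shared Y = X x Z serves both triads;
#' `kneeACSf_X = Y x Z` and `hipACSm_Z = X x Y`.
#'
#' @param head [fit_sphere()] of the femoral head patch.
#' @param condyles [fit_cylinder()] of the condylar patch, axis sign-resolved
#'   (right positive laterally, left positive medially).
#' @param side `"right"` or `"left"`.
#' @return named list `hipACSm`, `kneeACSf`.
#' @export
build_femoral_acs <- function(head, condyles, side) {
  side <- match.arg(side, c("right", "left"))
  o_hip <- head$centroid
  o_knee <- condyles$centroid
  X_hip <- if (side == "right") unit3(o_knee - o_hip) else unit3(o_hip - o_knee)
  Z_knee <- unit3(condyles$axis)
  check_t_parallel(X_hip, Z_knee, "femoral ACS")
  Y <- unit3(cross3(X_hip, Z_knee))
  X_knee <- cross3(Y, Z_knee)
  Z_hip <- cross3(X_hip, Y)
  list(hipACSm = acs("hipACSm", side, o_hip, X_hip, Y, Z_hip),
       kneeACSf = acs("kneeACSf", side, o_knee, X_knee, Y, Z_knee))
}

#' Build the crural ACSs from the proximal plane and distal cylinder
#'
#' Mirrors the femoral pattern with the crural sign conventions: the crural
#' long axis (`kneeACSm_X`) runs from the proximal plane centroid to the
#' distal cylinder centroid on the right (positive distally; reversed on the
#' left); the distal cylinder axis (sign-resolved right-medial /
#' left-lateral) is `ankleACSf_Z`; Y = X x Z on both sides (right positive
#' cranially); `ankleACSf_X = Y x Z`, `kneeACSm_Z = X x Y`.
#'
#' @param prox_plane [fit_plane()] of the proximal articular surfaces.
#' @param distal_cyl [fit_cylinder()] of the tibiotarsal condyles (mesotarsal)
#'   or astragalo-calcaneal rollers (crurotarsal), axis sign-resolved.
#' @param side `"right"` or `"left"`.
#' @return named list `kneeACSm`, `ankleACSf`.
#' @export
build_crural_acs <- function(prox_plane, distal_cyl, side) {
  side <- match.arg(side, c("right", "left"))
  o_knee <- prox_plane$centroid
  o_ankle <- distal_cyl$centroid
  X_knee <- if (side == "right") unit3(o_ankle - o_knee) else unit3(o_knee - o_ankle)
  Z_ankle <- unit3(distal_cyl$axis)
  check_t_parallel(X_knee, Z_ankle, "crural ACS")
  Y <- unit3(cross3(X_knee, Z_ankle))
  X_ankle <- cross3(Y, Z_ankle)
  Z_knee <- cross3(X_knee, Y)
  list(kneeACSm = acs("kneeACSm", side, o_knee, X_knee, Y, Z_knee),
       ankleACSf = acs("ankleACSf", side, o_ankle, X_ankle, Y, Z_ankle))
}

# Shared pedal axis math: X along the pedal long axis, Y = X x transverse,
# Z = X x Y.
pedal_axes <- function(prox_centroid, distal_point, transverse, side, what) {
  X <- if (side == "right") unit3(distal_point - prox_centroid)
       else unit3(prox_centroid - distal_point)
  transverse <- unit3(transverse)
  check_t_parallel(X, transverse, what)
  Y <- unit3(cross3(X, transverse))
  Z <- cross3(X, Y)
  acs("ankleACSm", side, prox_centroid, X, Y, Z)
}

#' Build the static pedal ACS (fused or tightly bound metatarsals)
#'
#' For feet with a fused tarsometatarsus the ACS is fixed to the segment:
#' the long axis runs from the proximal-plane centroid to the metatarsal-III
#' condylar cylinder centroid (right positive distally, left reversed), the
#' condylar cylinder axis is the pedal transverse axis, and
#' Y = X x transverse (right positive caudally), Z = X x Y (right positive
#' medially).
#'
#' @param prox_plane [fit_plane()] of the proximal articular surface.
#' @param mtIII_condyle [fit_cylinder()] of the metatarsal-III condyle, axis
#'   sign-resolved (right positive laterally, left positive medially).
#' @param side `"right"` or `"left"`.
#' @return an [acs()] named `ankleACSm`.
#' @export
build_pedal_acs_static <- function(prox_plane, mtIII_condyle, side) {
  side <- match.arg(side, c("right", "left"))
  pedal_axes(prox_plane$centroid, mtIII_condyle$centroid,
             mtIII_condyle$axis, side, "static pedal ACS")
}

#' Build the dynamic pedal ACS from per-pose outer-metatarsal landmarks
#'
#' For unfused, mobile metatarsals the pedal coordinate system is recomputed
#' every frame: the distal point is the midpoint of the medial-most and
#' lateral-most metatarsal condylar landmarks (cylinder centroids or any
#' consistently trackable point pair), and the transverse axis runs from the
#' medial to the lateral landmark on the right (reversed on the left).
#'
#' @param prox_plane_centroid 3-vector: proximal plane centroid, same frame
#'   as the landmarks (typically world coordinates of the current pose).
#' @param medial_pt,lateral_pt 3-vectors: outer metatarsal condylar
#'   landmarks.
#' @param side `"right"` or `"left"`.
#' @return an [acs()] named `ankleACSm`.
#' @export
build_pedal_acs_dynamic <- function(prox_plane_centroid, medial_pt,
                                    lateral_pt, side) {
  side <- match.arg(side, c("right", "left"))
  medial_pt <- as.numeric(medial_pt)
  lateral_pt <- as.numeric(lateral_pt)
  if (vnorm(lateral_pt - medial_pt) < 1e-12)
    stop("medial and lateral pedal landmarks coincide", call. = FALSE)
  transverse <- if (side == "right") lateral_pt - medial_pt
                else medial_pt - lateral_pt
  pedal_axes(as.numeric(prox_plane_centroid),
             (medial_pt + lateral_pt) / 2, transverse, side,
             "dynamic pedal ACS")
}

#' Signed agreement between ACS axes and anatomical proxy directions
#'
#' For each declared proxy (e.g. `lateral = c(0, 1, 0)`), reports the dot
#' product of the named ACS axis with the proxy and whether it is positive.
#' Proxies are sanity assertions only; they never enter axis construction.
#'
#' @param a an [acs()].
#' @param expectations named list mapping axis (`"X"`, `"Y"`, `"Z"`) to a
#'   proxy unit 3-vector the axis should point along (positive dot).
#' @return data.frame with columns `acs`, `axis`, `dot`, `ok`.
#' @export
acs_direction_report <- function(a, expectations) {
  rows <- lapply(names(expectations), function(ax) {
    d <- sum(acs_axis(a, ax) * unit3(as.numeric(expectations[[ax]])))
    data.frame(acs = a$name, side = a$side, axis = ax, dot = d, ok = d > 0)
  })
  do.call(rbind, rows)
}

#' Serialize a set of ACSs to JSON (origins and axes)
#'
#' @param acs_list named list of [acs()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_acs_json <- function(acs_list, path) {
  obj <- lapply(acs_list, function(a) {
    list(name = a$name, side = a$side, origin = a$origin,
         X = a$axes[, "X"], Y = a$axes[, "Y"], Z = a$axes[, "Z"])
  })
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a set of ACSs from JSON
#'
#' @param path path written by [write_acs_json()].
#' @return named list of [acs()] objects.
#' @export
read_acs_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(obj, function(e) {
    acs(e$name[[1]], e$side[[1]], as.numeric(e$origin),
        as.numeric(e$X), as.numeric(e$Y), as.numeric(e$Z))
  })
}
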