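# Joint coordinate systems (JCS): Grood-Suntay-style measurement of a mobile
# ACS relative to a fixed ACS. JCS_Z is the fixed ACS Z (flexion-extension),
# JCS_X is the mobile ACS X (long-axis rotation), and a floating JCS_Y stays
# orthogonal to both (abduction-adduction). Rotations decompose as intrinsic
# Z-Y-X Tait-Bryan angles; translations are components of the inter-origin
# vector along the *fixed ACS* axes (not the JCS axes, which need not be
# mutually orthogonal).

jcs_pairing <- function() {
  list(pelvis = c(fixed = "pelvicACSf", mobile = "pelvicACSm"),
       hip = c(fixed = "hipACSf", mobile = "hipACSm"),
       knee = c(fixed = "kneeACSf", mobile = "kneeACSm"),
       ankle = c(fixed = "ankleACSf", mobile = "ankleACSm"))
}

#' Construct a joint coordinate system
#'
#' @param joint `"pelvis"` (ground pseudo-joint), `"hip"`, `"knee"`, or
#'   `"ankle"`.
#' @param side `"right"` or `"left"` (`"midline"` for the pelvis).
#' @param fixed the fixed (proximal) [acs()], in its segment's local frame.
#' @param mobile the mobile (distal) [acs()], in its segment's local frame.
#' @return object of class `jcs`.
#' @export
jcs <- function(joint, side, fixed, mobile) {
  joint <- match.arg(joint, c("pelvis", "hip", "knee", "ankle"))
  expected <- jcs_pairing()[[joint]]
  if (fixed$name != expected["fixed"] || mobile$name != expected["mobile"])
    stop("joint '", joint, "' pairs ", expected["fixed"], " (fixed) with ",
         expected["mobile"], " (mobile); got ", fixed$name, " / ",
         mobile$name, call. = FALSE)
  structure(list(joint = joint, side = side, fixed = fixed, mobile = mobile),
            class = "jcs")
}

#' @export
print.jcs <- function(x, ...) {
  cat("jcs:", x$joint, paste0("(", x$side, "), "),
      x$fixed$name, "->", x$mobile$name, "\n")
  invisible(x)
}

#' Construct the ground-based pelvic fixed ACS
#'
#' A non-anatomical coordinate system on the ground surface from which pelvic
#' motion is referenced: Z is exactly world-up, X and Y are horizontal, and
#' the heading of X in the horizontal plane is user-defined (a common choice
#' is the animal's mean direction of travel).
#'
#' @param origin 3-vector on the ground surface (mm).
#' @param heading horizontal 3-vector giving the X direction (its vertical
#'   component is removed).
#' @return an [acs()] named `pelvicACSf`.
#' @export
ground_acs <- function(origin = c(0, 0, 0), heading = c(1, 0, 0)) {
  Z <- c(0, 0, 1)
  h <- as.numeric(heading)
  h[3] <- 0
  if (vnorm(h) < 1e-12)
    stop("ground heading must have a horizontal component", call. = FALSE)
  X <- unit3(h)
  Y <- cross3(Z, X)
  acs("pelvicACSf", "ground", origin, X, Y, Z)
}

#' Decompose relative bone pose into six JCS degrees of freedom
#'
#' Expresses both ACSs in world coordinates through their segment transforms,
#' forms the relative rotation `R_rel = F' M` (F, M the world axis triads of
#' the fixed and mobile ACS), decomposes it as intrinsic Z-Y-X Tait-Bryan
#' angles (FE about JCS_Z, ABAD about the floating JCS_Y, LAR about JCS_X),
#' and measures translations of the mobile origin from the fixed origin along
#' the fixed-ACS axes. When the frames are registered all six values are 0.
#' At |ABAD| = 90 degrees the FE and LAR axes are collinear, so the two are
#' not individually unique: the record is flagged and, by convention, the
#' determined combination is reported as FE with LAR = 0.
#'
#' @param j a [jcs()].
#' @param T_fixed,T_mobile [rigid_transform()]s of the fixed and mobile
#'   segments (local -> world).
#' @param frame_index frame number recorded in the output.
#' @return a [joint_pose_record()].
#' @export
decompose_pose <- function(j, T_fixed, T_mobile, frame_index = 0L) {
  Fw <- acs_world(j$fixed, T_fixed)
  Mw <- acs_world(j$mobile, T_mobile)
  R_rel <- crossprod(Fw$axes, Mw$axes)
  e <- euler_zyx(R_rel)
  tr <- as.vector(crossprod(Fw$axes, Mw$origin - Fw$origin))
  joint_pose_record(j$joint, jcs_record_side(j), frame_index,
                    FE_deg = e$rz_deg, ABAD_deg = e$ry_deg,
                    LAR_deg = e$rx_deg,
                    t_x_mm = tr[1], t_y_mm = tr[2], t_z_mm = tr[3],
                    gimbal_flag = e$gimbal)
}

jcs_record_side <- function(j) {
  if (j$side %in% c("right", "left")) j$side
  else if (j$mobile$side %in% c("right", "left")) j$mobile$side
  else "right"
}

#' Forward kinematics: segment transform realizing a JCS pose
#'
#' Inverse of [decompose_pose()]: given the fixed segment's transform and a
#' six-DOF pose, returns the mobile segment's world transform such that
#' decomposition reproduces the pose exactly. Poses with |ABAD| >= 90 degrees
#' are outside the principal decomposition range and are rejected.
#'
#' @param j a [jcs()].
#' @param pose a [joint_pose_record()] (or any list with `FE_deg`,
#'   `ABAD_deg`, `LAR_deg`, `t_x_mm`, `t_y_mm`, `t_z_mm`).
#' @param T_fixed the fixed segment's [rigid_transform()].
#' @return the mobile segment's [rigid_transform()].
#' @export
compose_pose <- function(j, pose, T_fixed) {
  if (abs(pose$ABAD_deg) >= 90)
    stop("|ABAD| >= 90 degrees is outside the principal decomposition range",
         call. = FALSE)
  Fw <- acs_world(j$fixed, T_fixed)
  M_axes <- Fw$axes %*% rot_zyx(pose$FE_deg, pose$ABAD_deg, pose$LAR_deg)
  M_origin <- Fw$origin +
    as.vector(Fw$axes %*% c(pose$t_x_mm, pose$t_y_mm, pose$t_z_mm))
  Rm <- M_axes %*% t(j$mobile$axes)
  # re-symmetrize against accumulated round-off
  sv <- svd(Rm)
  Rm <- sv$u %*% t(sv$v)
  rigid_transform(Rm, M_origin - as.vector(Rm %*% j$mobile$origin))
}

#' World directions of the three JCS rotation axes
#'
#' JCS_Z rides with the fixed segment, JCS_X with the mobile segment, and
#' JCS_Y floats orthogonal to both (`unit(Z x X)`).
#'
#' @inheritParams decompose_pose
#' @return list of unit 3-vectors `Z`, `Y`, `X` in world coordinates.
#' @export
jcs_world_axes <- function(j, T_fixed, T_mobile) {
  Zw <- as.vector(T_fixed$R %*% acs_axis(j$fixed, "Z"))
  Xw <- as.vector(T_mobile$R %*% acs_axis(j$mobile, "X"))
  cr <- cross3(Zw, Xw)
  Yw <- if (vnorm(cr) < 1e-12) rep(NA_real_, 3) else unit3(cr)
  list(Z = Zw, Y = Yw, X = Xw)
}

#' Locate the gimbal singularity of a JCS numerically
#'
#' Sweeps the second (ABAD) rotation upward from zero through
#' [compose_pose()], monitoring the world-frame angle between JCS_Z and
#' JCS_X as lines. The first sweep point where that angle drops below
#' `threshold_rad` brackets the singularity; secant iteration on the
#' (linearly vanishing) angle then polishes to the true collinearity point,
#' where FE and LAR axes coincide and a rotational degree of freedom is
#' lost.
#'
#' @param j a [jcs()]; defaults to a right-angle toy joint.
#' @param threshold_rad collinearity detection threshold (radians).
#' @param step_deg sweep step (degrees).
#' @return list: `singular_abad_deg` (polished collinearity angle),
#'   `threshold_crossing_deg` (first sweep angle below threshold),
#'   `min_angle_rad` (line angle at the polished point).
#' @export
find_gimbal_singularity <- function(j = NULL, threshold_rad = 1e-6,
                                    step_deg = 0.5) {
  if (is.null(j)) {
    fixed <- acs("hipACSf", "right", c(0, 0, 0),
                 c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    mobile <- acs("hipACSm", "right", c(0, 0, 0),
                  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    j <- jcs("hip", "right", fixed, mobile)
  }
  Tf <- rigid_transform()
  angle_at <- function(abad) {
    pose <- list(FE_deg = 0, ABAD_deg = abad, LAR_deg = 0,
                 t_x_mm = 0, t_y_mm = 0, t_z_mm = 0)
    Tm <- compose_pose(j, pose, Tf)
    ax <- jcs_world_axes(j, Tf, Tm)
    line_angle(ax$Z, ax$X)
  }
  sweep <- seq(0, 90 - 1e-9, by = step_deg)
  below <- NA_real_
  prev <- sweep[1]
  for (b in sweep) {
    if (angle_at(b) < threshold_rad) {
      below <- b
      break
    }
    prev <- b
  }
  if (is.na(below)) {
    # grid never reaches the threshold: it lies between the last grid point
    # and 90; bisect the crossing there
    prev <- sweep[length(sweep)]
    below <- 90 - 1e-12
  }
  crossing <- stats::uniroot(function(b) angle_at(b) - threshold_rad,
                             c(prev, below), tol = 1e-12)$root
  # polish from the crossing to the true collinearity point (angle -> 0) by
  # secant iteration; the line angle vanishes linearly in ABAD
  b0 <- prev; b1 <- crossing
  f0 <- angle_at(b0); f1 <- angle_at(b1)
  for (i in 1:60) {
    if (abs(f1 - f0) < 1e-300) break
    b2 <- b1 - f1 * (b1 - b0) / (f1 - f0)
    b2 <- min(b2, 90 - 1e-12)  # stay inside the composable range
    if (abs(b2 - b1) < 1e-12) { b1 <- b2; break }
    b0 <- b1; f0 <- f1
    b1 <- b2; f1 <- angle_at(b1)
  }
  list(singular_abad_deg = b1,
       threshold_crossing_deg = crossing,
       min_angle_rad = angle_at(min(b1, 90 - 1e-12)))
}

# Anatomical meaning of a positive rotation, per joint. The knee's reversed
# ABAD convention (adduction positive) is what keeps its triads right-handed
# while preserving equal-sign FE and LAR between sides.
jcs_sign_table <- function() {
  list(
    pelvis = list(FE = c(pos = "yaw left", neg = "yaw right"),
                  ABAD = c(pos = "pitch up", neg = "pitch down"),
                  LAR = c(pos = "roll right-up", neg = "roll left-up")),
    hip = list(FE = c(pos = "extension", neg = "flexion"),
               ABAD = c(pos = "abduction", neg = "adduction"),
               LAR = c(pos = "external", neg = "internal")),
    knee = list(FE = c(pos = "extension", neg = "flexion"),
                ABAD = c(pos = "adduction", neg = "abduction"),
                LAR = c(pos = "external", neg = "internal")),
    ankle = list(FE = c(pos = "extension", neg = "flexion"),
                 ABAD = c(pos = "abduction", neg = "adduction"),
                 LAR = c(pos = "external", neg = "internal")))
}

#' Attach anatomical direction labels to a pose record
#'
#' Translates signed rotation values into the anatomical vocabulary of each
#' joint (e.g. +5 degrees ABAD at the hip is "abduction 5 deg", but at the
#' knee it is "adduction 5 deg" because of the knee's reversed ABAD
#' convention). Raw numbers are unchanged; labels are added as columns
#' `FE_label`, `ABAD_label`, `LAR_label`. Zero values are labelled
#' `"neutral"`.
#'
#' @param record a [joint_pose_record()] or pose-table data.frame.
#' @param zero_tol magnitude below which a rotation counts as neutral.
#' @return the record with three label columns added.
#' @export
label_pose <- function(record, zero_tol = 1e-12) {
  tab <- jcs_sign_table()
  lab1 <- function(joint, comp, value) {
    if (!joint %in% names(tab)) stop("unknown joint: ", joint, call. = FALSE)
    if (abs(value) <= zero_tol) return("neutral")
    word <- tab[[joint]][[comp]][if (value > 0) "pos" else "neg"]
    sprintf("%s %.6g deg", word, abs(value))
  }
  record$FE_label <- mapply(lab1, record$joint, "FE", record$FE_deg)
  record$ABAD_label <- mapply(lab1, record$joint, "ABAD", record$ABAD_deg)
  record$LAR_label <- mapply(lab1, record$joint, "LAR", record$LAR_deg)
  record
}

#' Measure pelvic pose relative to the ground ACS
#'
#' The pelvis-ground pseudo-joint uses the same Z-Y-X machinery; rotations
#' are reported as yaw (about pelvicJCS_Z, counter-clockwise/left positive),
#' pitch (about the floating Y, nose-up positive) and roll (about
#' pelvicJCS_X, right-acetabulum-up positive), in the FE/ABAD/LAR columns
#' respectively. Translations are displacements of the pelvicACSm origin
#' along the ground-ACS axes.
#'
#' @param ground a [ground_acs()].
#' @param pelvic_acsm the pelvis's [acs()] in pelvis-local coordinates.
#' @param T_pelvis the pelvis [rigid_transform()] (local -> world).
#' @param frame_index frame number for the record.
#' @return a labelled [joint_pose_record()].
#' @export
pelvic_pose <- function(ground, pelvic_acsm, T_pelvis, frame_index = 0L) {
  j <- jcs("pelvis", "midline", ground, pelvic_acsm)
  rec <- decompose_pose(j, rigid_transform(), T_pelvis, frame_index)
  label_pose(rec)
}
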