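# Synthetic-limb fixture generator: parametric archosaur-like bones whose
# labelled articular patches lie exactly on known primitives, plus gait-like
# joint trajectories and the transform sequences they imply. Everything the
# main pipeline consumes (OBJ, patch JSON, transform CSV, config) can be
# produced here with exact ground truth, so the whole chain is testable
# without any specimen data.
#
# Default dimensions approximate an adult guineafowl hindlimb (mm); the
# unfused (crocodylian-like) pes is selected with `fused = FALSE`.

#' Blueprint for a synthetic hindlimb
#'
#' @param sides which limbs to generate (`"right"`, `"left"`, or both).
#' @param fused logical: fused tarsometatarsus (avian, static pedal ACS) or
#'   unfused outer metatarsals (crocodylian-like, dynamic pedal ACS). An
#'   unfused blueprint still carries a metatarsal-III condyle so the static
#'   variant can be computed for comparison.
#' @param femur_length,crus_length,pes_length segment lengths (mm).
#' @param acet_sep distance between acetabular sphere centroids (mm).
#' @param acet_radius,head_radius,condyle_radius,sacral_radius,crus_prox_radius,crus_distal_radius,pes_prox_radius,pes_condyle_radius primitive radii (mm).
#' @param sacral_length sacral cylinder patch length (mm).
#' @param condyle_width,crus_distal_width,pes_condyle_width axial extent of
#'   the cylinder patches (mm).
#' @param condylar_skew_deg angle between the femoral condylar axis and the
#'   plane normal to the femoral long axis (deg); nonzero values reproduce
#'   the skew that makes the crus non-parallel to the femur in the
#'   reference pose.
#' @param condyle_spacing distance between the outermost metatarsal condylar
#'   centroids (mm), unfused pes only.
#' @param resolution angular subdivisions of the primitive meshes (>= 8).
#'   The default of 128 gives a few thousand vertices per articular patch,
#'   approximating the polygon density of CT-derived bone models; coarser
#'   settings are adequate wherever noise-free exactness rather than
#'   estimation error is of interest.
#' @param noise_sd isotropic Gaussian noise added to every mesh vertex (mm);
#'   0 keeps patches exactly on their primitives.
#' @param seed RNG seed recorded in all outputs; drives noise only.
#' @return object of class `limb_blueprint`.
#' @export
limb_blueprint <- function(sides = "right", fused = TRUE,
                           femur_length = 70, crus_length = 110,
                           pes_length = 55,
                           acet_sep = 40, acet_radius = 6,
                           sacral_radius = 5, sacral_length = 35,
                           head_radius = 6, condyle_radius = 7,
                           condyle_width = 12, condylar_skew_deg = 15,
                           crus_prox_radius = 8, crus_distal_radius = 5,
                           crus_distal_width = 12,
                           pes_prox_radius = 5, pes_condyle_radius = 4,
                           pes_condyle_width = 6, condyle_spacing = 24,
                           resolution = 128, noise_sd = 0, seed = 1) {
  sides <- match.arg(sides, c("right", "left"), several.ok = TRUE)
  bp <- list(sides = sides, fused = fused,
             femur_length = femur_length, crus_length = crus_length,
             pes_length = pes_length,
             acet_sep = acet_sep, acet_radius = acet_radius,
             sacral_radius = sacral_radius, sacral_length = sacral_length,
             head_radius = head_radius, condyle_radius = condyle_radius,
             condyle_width = condyle_width,
             condylar_skew_deg = condylar_skew_deg,
             crus_prox_radius = crus_prox_radius,
             crus_distal_radius = crus_distal_radius,
             crus_distal_width = crus_distal_width,
             pes_prox_radius = pes_prox_radius,
             pes_condyle_radius = pes_condyle_radius,
             pes_condyle_width = pes_condyle_width,
             condyle_spacing = condyle_spacing,
             resolution = as.integer(resolution), noise_sd = noise_sd,
             seed = as.integer(seed))
  lens <- c(femur_length, crus_length, pes_length, acet_sep, sacral_length)
  if (any(lens <= 0)) stop("lengths must be positive", call. = FALSE)
  if (bp$resolution < 8L) stop("resolution must be >= 8", call. = FALSE)
  if (condyle_radius > femur_length / 2)
    stop("infeasible geometry: condyle radius exceeds half the femur length",
         call. = FALSE)
  if (crus_distal_radius > crus_length / 2 ||
      pes_condyle_radius > pes_length / 2)
    stop("infeasible geometry: distal radius exceeds half the segment length",
         call. = FALSE)
  if (!fused && condyle_spacing <= 2 * pes_condyle_radius)
    stop("infeasible geometry: outer metatarsal condyles overlap",
         call. = FALSE)
  structure(bp, class = "limb_blueprint")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# --- per-segment geometry (right-side local frames) -----------------------
# pelvis: +x cranial, +y left, +z dorsal; acetabular centroids on the y axis
# femur:  condylar centroid at the origin, +z proximal (head at (0,0,L)),
#         +y lateral
# crus:   distal (ankle) cylinder centroid at the origin, +z proximal
# pes:    distal condyles at the origin, +z proximal; plane centroid (0,0,L)

synth_pelvis <- function(bp) {
  res <- bp$resolution
  hw <- bp$acet_sep / 2
  oR <- c(0, -hw, 0); oL <- c(0, hw, 0)
  sac_centre <- c(0, 0, hw * 0.75)
  b <- new_mesh_builder()
  b <- builder_add(b, sphere_cap_mesh(oR, bp$acet_radius, c(0, -1, 0), 70,
                                      n_phi = max(4, res %/% 3), n_theta = res),
                   "acetabulum_R")
  b <- builder_add(b, sphere_cap_mesh(oL, bp$acet_radius, c(0, 1, 0), 70,
                                      n_phi = max(4, res %/% 3), n_theta = res),
                   "acetabulum_L")
  b <- builder_add(b, cylinder_band_mesh(sac_centre, c(1, 0, 0),
                                         bp$sacral_radius, bp$sacral_length,
                                         n_circ = res, n_len = max(4, res %/% 3)),
                   "sacral_centra")
  refs <- list(sacral_centra = c(1, 0, 0))
  truth <- list(
    acetabulum_R = list(type = "sphere", centroid = oR, radius = bp$acet_radius),
    acetabulum_L = list(type = "sphere", centroid = oL, radius = bp$acet_radius),
    sacral_centra = list(type = "cylinder", centroid = sac_centre,
                         axis = c(1, 0, 0), radius = bp$sacral_radius))
  list(builder = b, refs = refs, truth = truth)
}

synth_femur <- function(bp) {
  res <- bp$resolution
  sk <- bp$condylar_skew_deg * DEG2RAD
  cond_axis <- c(0, cos(sk), sin(sk))
  head_c <- c(0, 0, bp$femur_length)
  b <- new_mesh_builder()
  b <- builder_add(b, sphere_cap_mesh(head_c, bp$head_radius, c(0, 0, 1), 70,
                                      n_phi = max(4, res %/% 3), n_theta = res),
                   "femoral_head")
  b <- builder_add(b, cylinder_band_mesh(c(0, 0, 0), cond_axis,
                                         bp$condyle_radius, bp$condyle_width,
                                         n_circ = res,
                                         n_len = max(4, res %/% 3),
                                         arc_deg = 160,
                                         arc_centre = c(0, 0, -1)),
                   "femoral_condyles")
  shaft <- cylinder_band_mesh(c(0, 0, bp$femur_length / 2), c(0, 0, 1),
                              bp$condyle_radius * 0.45,
                              bp$femur_length * 0.75,
                              n_circ = max(8, res %/% 2), n_len = 2)
  b <- builder_add(b, shaft)
  refs <- list(femoral_condyles = c(0, 1, 0))  # right: positive laterally
  truth <- list(
    femoral_head = list(type = "sphere", centroid = head_c,
                        radius = bp$head_radius),
    femoral_condyles = list(type = "cylinder", centroid = c(0, 0, 0),
                            axis = cond_axis, radius = bp$condyle_radius))
  list(builder = b, refs = refs, truth = truth)
}

synth_crus <- function(bp) {
  res <- bp$resolution
  prox_c <- c(0, 0, bp$crus_length)
  b <- new_mesh_builder()
  b <- builder_add(b, disk_mesh(prox_c, c(0, 0, 1), bp$crus_prox_radius,
                                n_ring = max(3, res %/% 5), n_theta = res),
                   "crus_proximal")
  b <- builder_add(b, cylinder_band_mesh(c(0, 0, 0), c(0, -1, 0),
                                         bp$crus_distal_radius,
                                         bp$crus_distal_width,
                                         n_circ = res,
                                         n_len = max(4, res %/% 3),
                                         arc_deg = 170,
                                         arc_centre = c(0, 0, -1)),
                   "crus_distal")
  shaft <- cylinder_band_mesh(c(0, 0, bp$crus_length / 2), c(0, 0, 1),
                              bp$crus_distal_radius * 0.6,
                              bp$crus_length * 0.8,
                              n_circ = max(8, res %/% 2), n_len = 2)
  b <- builder_add(b, shaft)
  refs <- list(crus_proximal = c(0, 0, 1),
               crus_distal = c(0, -1, 0))  # right: positive medially
  truth <- list(
    crus_proximal = list(type = "plane", centroid = prox_c,
                         normal = c(0, 0, 1)),
    crus_distal = list(type = "cylinder", centroid = c(0, 0, 0),
                       axis = c(0, -1, 0), radius = bp$crus_distal_radius))
  list(builder = b, refs = refs, truth = truth)
}

synth_pes <- function(bp) {
  res <- bp$resolution
  prox_c <- c(0, 0, bp$pes_length)
  d <- bp$condyle_spacing / 2
  b <- new_mesh_builder()
  b <- builder_add(b, disk_mesh(prox_c, c(0, 0, 1), bp$pes_prox_radius,
                                n_ring = max(3, res %/% 5), n_theta = res),
                   "pes_proximal")
  add_condyle <- function(b, centre, label) {
    builder_add(b, cylinder_band_mesh(centre, c(0, 1, 0),
                                      bp$pes_condyle_radius,
                                      bp$pes_condyle_width,
                                      n_circ = res,
                                      n_len = max(4, res %/% 3),
                                      arc_deg = 180,
                                      arc_centre = c(0, 0, -1)), label)
  }
  b <- add_condyle(b, c(0, 0, 0), "pes_distal")  # metatarsal III
  refs <- list(pes_proximal = c(0, 0, 1),
               pes_distal = c(0, 1, 0))  # right: positive laterally
  truth <- list(
    pes_proximal = list(type = "plane", centroid = prox_c,
                        normal = c(0, 0, 1)),
    pes_distal = list(type = "cylinder", centroid = c(0, 0, 0),
                      axis = c(0, 1, 0), radius = bp$pes_condyle_radius))
  if (!bp$fused) {
    b <- add_condyle(b, c(0, -d, 0), "pes_distal_medial")
    b <- add_condyle(b, c(0, d, 0), "pes_distal_lateral")
    refs$pes_distal_medial <- c(0, 1, 0)
    refs$pes_distal_lateral <- c(0, 1, 0)
    truth$pes_distal_medial <- list(type = "cylinder", centroid = c(0, -d, 0),
                                    axis = c(0, 1, 0),
                                    radius = bp$pes_condyle_radius)
    truth$pes_distal_lateral <- list(type = "cylinder", centroid = c(0, d, 0),
                                     axis = c(0, 1, 0),
                                     radius = bp$pes_condyle_radius)
  }
  shaft <- cylinder_band_mesh(c(0, 0, bp$pes_length / 2), c(0, 0, 1),
                              bp$pes_condyle_radius * 0.7,
                              bp$pes_length * 0.75,
                              n_circ = max(8, res %/% 2), n_len = 2)
  b <- builder_add(b, shaft)
  list(builder = b, refs = refs, truth = truth,
       landmarks = list(medial = c(0, -d, 0), lateral = c(0, d, 0)))
}

# Mirror a segment's truth primitives across the sagittal plane, re-resolving
# axis signs by the (numerically unchanged) reference directions.
mirror_truth <- function(truth, refs) {
  out <- lapply(names(truth), function(nm) {
    tr <- truth[[nm]]
    tr$centroid <- mirror_point_xz(tr$centroid)
    if (!is.null(tr$axis)) {
      ax <- mirror_point_xz(tr$axis)
      tr$axis <- flip_to_reference(ax, refs[[nm]])
    }
    if (!is.null(tr$normal)) tr$normal <- mirror_point_xz(tr$normal)
    tr
  })
  names(out) <- names(truth)
  out
}

finalize_segment <- function(part, side = NULL) {
  mesh <- builder_mesh(part$builder)
  labels <- part$builder$labels
  if (identical(side, "left")) {
    mesh <- mirror_mesh_xz(mesh)
    part$truth <- mirror_truth(part$truth, part$refs)
    if (!is.null(part$landmarks))
      part$landmarks <- lapply(part$landmarks, mirror_point_xz)
  }
  patches <- lapply(names(labels), function(nm)
    surface_patch(nm, labels[[nm]], mesh,
                  reference_direction = part$refs[[nm]]))
  names(patches) <- names(labels)
  list(mesh = mesh, patches = patches, truth = part$truth,
       landmarks = part$landmarks)
}

# ACS set derived directly from exact blueprint primitives (no fitting).
truth_acs_set <- function(segments, sides, fused) {
  pel <- segments$pelvis$truth
  acs_set <- build_pelvic_acs(pel$acetabulum_R, pel$acetabulum_L,
                              pel$sacral_centra)
  for (side in sides) {
    sfx <- side_suffix(side)
    fem <- segments[[paste0("femur_", side)]]$truth
    fa <- build_femoral_acs(fem$femoral_head, fem$femoral_condyles, side)
    cru <- segments[[paste0("crus_", side)]]$truth
    ca <- build_crural_acs(cru$crus_proximal, cru$crus_distal, side)
    pes <- segments[[paste0("pes_", side)]]
    pa <- build_pedal_acs_static(pes$truth$pes_proximal,
                                 pes$truth$pes_distal, side)
    acs_set[[paste0("hipACSm", sfx)]] <- fa$hipACSm
    acs_set[[paste0("kneeACSf", sfx)]] <- fa$kneeACSf
    acs_set[[paste0("kneeACSm", sfx)]] <- ca$kneeACSm
    acs_set[[paste0("ankleACSf", sfx)]] <- ca$ankleACSf
    acs_set[[paste0("ankleACSm", sfx)]] <- pa
  }
  acs_set
}

#' Generate a synthetic limb with exact ground truth
#'
#' Builds the pelvis, femur, crus and pes meshes of the blueprint with
#' labelled articular patches lying exactly on the stated primitives (before
#' optional noise), the patch reference directions, the ground-truth
#' primitive parameters, and the ACS set derived from that exact truth. Left
#' limbs are sagittal mirror images of right limbs with reference directions
#' re-derived. Deterministic given the blueprint seed.
#'
#' @param blueprint a [limb_blueprint()].
#' @return object of class `synthetic_limb`: `blueprint`, `segments` (each
#'   with `mesh`, `patches`, `truth`, and for the pes `landmarks`),
#'   `acs_truth` (ACS set for [assemble_reference_pose()] etc.), and
#'   `proxies` (anatomical direction proxies per segment, local frames).
#' @export
generate_limb <- function(blueprint) {
  stopifnot(inherits(blueprint, "limb_blueprint"))
  bp <- blueprint
  parts <- list(pelvis = synth_pelvis(bp))
  segments <- list(pelvis = finalize_segment(parts$pelvis))
  for (side in bp$sides) {
    segments[[paste0("femur_", side)]] <- finalize_segment(synth_femur(bp), side)
    segments[[paste0("crus_", side)]] <- finalize_segment(synth_crus(bp), side)
    segments[[paste0("pes_", side)]] <- finalize_segment(synth_pes(bp), side)
  }
  if (bp$noise_sd > 0) {
    segments <- with_seed(bp$seed, {
      lapply(segments, function(seg) {
        v <- seg$mesh$vertices
        seg$mesh$vertices <- v + matrix(stats::rnorm(length(v), 0, bp$noise_sd),
                                        nrow(v), 3)
        seg
      })
    })
  }
  proxies <- list(
    pelvis = list(cranial = c(1, 0, 0), left = c(0, 1, 0), dorsal = c(0, 0, 1)),
    femur_right = list(proximal = c(0, 0, 1), lateral = c(0, 1, 0)),
    femur_left = list(proximal = c(0, 0, 1), lateral = c(0, -1, 0)),
    crus_right = list(proximal = c(0, 0, 1), medial = c(0, -1, 0)),
    crus_left = list(proximal = c(0, 0, 1), medial = c(0, 1, 0)),
    pes_right = list(proximal = c(0, 0, 1), lateral = c(0, 1, 0)),
    pes_left = list(proximal = c(0, 0, 1), lateral = c(0, -1, 0)))
  structure(list(blueprint = bp, segments = segments,
                 acs_truth = truth_acs_set(segments, bp$sides, bp$fused),
                 proxies = proxies),
            class = "synthetic_limb")
}

#' @export
print.synthetic_limb <- function(x, ...) {
  cat("synthetic_limb:", paste(x$blueprint$sides, collapse = "+"),
      if (x$blueprint$fused) "fused pes" else "unfused pes",
      "| seed", x$blueprint$seed, "\n")
  for (nm in names(x$segments))
    cat(sprintf("  %-12s %5d vertices, %5d faces, %d patches\n", nm,
                nrow(x$segments[[nm]]$mesh$vertices),
                nrow(x$segments[[nm]]$mesh$faces),
                length(x$segments[[nm]]$patches)))
  invisible(x)
}

#' Write a synthetic limb to disk in the pipeline's interchange formats
#'
#' Emits `<segment>.obj`, `<segment>_patches.json` per segment plus
#' `config.yaml` (sides, pes mode, proxies, landmark coordinates, seed) and
#' `truth_synthetic.json` (the generating primitive parameters; synthetic
#' ground truth, not fitted values).
#'
#' @param limb a [generate_limb()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_limb_fixture <- function(limb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(limb$segments)) {
    seg <- limb$segments[[nm]]
    write_obj_mesh(seg$mesh, file.path(dir, paste0(nm, ".obj")))
    write_patches(seg$patches, file.path(dir, paste0(nm, "_patches.json")))
  }
  lm <- lapply(limb$segments[grep("^pes_", names(limb$segments))],
               function(s) s$landmarks)
  cfg <- list(
    units = "mm",
    sides = limb$blueprint$sides,
    pes_mode = if (limb$blueprint$fused) "static" else "dynamic",
    seed = limb$blueprint$seed,
    segments = lapply(names(limb$segments), function(nm)
      list(name = nm, mesh = paste0(nm, ".obj"),
           patches = paste0(nm, "_patches.json"))),
    proxies = limb$proxies,
    pedal_landmarks_local = lm)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  truth <- lapply(limb$segments, `[[`, "truth")
  jsonlite::write_json(truth, file.path(dir, "truth_synthetic.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Construct a gait script
#'
#' Per-joint six-DOF time series plus a pelvis trajectory, the input to
#' [animate_limb()]. ABAD magnitudes above 85 degrees are rejected unless
#' `stress = TRUE` (singularity-stress trials).
#'
#' @param pelvis data.frame with columns `yaw, pitch, roll, tx, ty, tz`
#'   (deg/mm), one row per frame.
#' @param hip,knee,ankle data.frames with columns
#'   `FE, ABAD, LAR, tx, ty, tz`, one row per frame.
#' @param pedal optional data.frame with `spread_mm`, `skew_mm` per frame
#'   (unfused feet): symmetric outward spread of the outer metatarsal
#'   condyles and their opposed cranio-caudal skew.
#' @param stress allow |ABAD| > 85 degrees.
#' @return object of class `gait_script`.
#' @export
gait_script <- function(pelvis, hip, knee, ankle, pedal = NULL,
                        stress = FALSE) {
  n <- nrow(pelvis)
  for (df in list(hip, knee, ankle))
    if (nrow(df) != n) stop("all joint series must have equal length",
                            call. = FALSE)
  if (!stress) {
    mx <- max(abs(hip$ABAD), abs(knee$ABAD), abs(ankle$ABAD),
              abs(pelvis$pitch))
    if (mx > 85)
      stop("|ABAD|/|pitch| exceeds 85 degrees; use stress = TRUE for ",
           "singularity-stress trials", call. = FALSE)
  }
  structure(list(n_frames = n, pelvis = pelvis, hip = hip, knee = knee,
                 ankle = ankle, pedal = pedal, stress = stress),
            class = "gait_script")
}

#' A smooth cyclic default gait script
#'
#' One stride of sinusoidal joint excursions with guineafowl-like midline
#' values, well inside the |ABAD| < 85 degree singularity bound, plus a
#' forward pelvis path. Amplitudes are fixed; only the frame count and the
#' optional pedal spread/skew cycle (for unfused feet) vary.
#'
#' @param n_frames number of frames.
#' @param pedal_spread_mm,pedal_skew_mm amplitudes of the sinusoidal outer
#'   metatarsal spread and skew (mm); both zero gives frozen metatarsals.
#' @return a [gait_script()].
#' @export
default_gait_script <- function(n_frames = 20, pedal_spread_mm = 0,
                                pedal_skew_mm = 0) {
  ph <- 2 * pi * (seq_len(n_frames) - 1) / n_frames
  pelvis <- data.frame(yaw = 4 * sin(ph), pitch = 12 + 3 * sin(ph + 0.5),
                       roll = 3 * sin(2 * ph),
                       tx = 220 * (seq_len(n_frames) - 1) / n_frames,
                       ty = 4 * sin(ph), tz = 140 + 6 * sin(2 * ph))
  hip <- data.frame(FE = 45 + 25 * sin(ph), ABAD = 12 + 6 * sin(ph + 1),
                    LAR = 8 * sin(ph + 2), tx = 0.4 * sin(ph),
                    ty = 0.3 * sin(ph + 1), tz = 0.3 * sin(ph + 2))
  knee <- data.frame(FE = 70 + 30 * sin(ph + 0.8), ABAD = 6 * sin(ph),
                     LAR = 5 * sin(ph + 1), tx = 0.3 * sin(ph),
                     ty = 0.2 * sin(ph), tz = 0.2 * sin(ph + 1))
  ankle <- data.frame(FE = 55 + 28 * sin(ph + 1.6), ABAD = 5 + 4 * sin(ph),
                      LAR = 4 * sin(ph + 0.5), tx = 0.2 * sin(ph),
                      ty = 0.2 * sin(ph + 1), tz = 0.1 * sin(ph))
  pedal <- data.frame(spread_mm = pedal_spread_mm * (1 - cos(ph)) / 2,
                      skew_mm = pedal_skew_mm * sin(ph))
  gait_script(pelvis, hip, knee, ankle, pedal)
}

script_record <- function(df, i) {
  list(FE_deg = df$FE[i], ABAD_deg = df$ABAD[i], LAR_deg = df$LAR[i],
       t_x_mm = df$tx[i], t_y_mm = df$ty[i], t_z_mm = df$tz[i])
}

#' Animate a synthetic limb along a gait script
#'
#' Forward kinematics: starting from the ground, composes each scripted
#' joint pose down the pelvis-femur-crus-pes chain using the limb's exact
#' ground-truth ACSs, yielding per-segment transform sequences whose
#' decomposition reproduces the script. The same script drives both sides;
#' because the ACSs are constructed asymmetrically, equal scripted values
#' produce mirror-equivalent motion of the two limbs. For unfused feet the
#' per-frame world positions of the outer metatarsal condylar landmarks are
#' also emitted (with the scripted spread/skew applied within the pes
#' segment frame).
#'
#' @param limb a [generate_limb()] result.
#' @param script a [gait_script()].
#' @param ground a [ground_acs()].
#' @return list: `sequences` (named [transform_sequence()] list keyed
#'   `"<segment>_<side>"`), `pedal_landmarks` (per side, world-frame
#'   data.frame, unfused blueprints only), `script`, `ground`.
#' @export
animate_limb <- function(limb, script, ground = ground_acs()) {
  stopifnot(inherits(limb, "synthetic_limb"), inherits(script, "gait_script"))
  bp <- limb$blueprint
  n <- script$n_frames
  frames <- seq_len(n)
  ident <- rigid_transform()
  sequences <- list()
  landmarks <- list()
  for (side in bp$sides) {
    jset <- limb_jcs(limb$acs_truth, ground, side)
    T_pel <- vector("list", n); T_fem <- vector("list", n)
    T_cru <- vector("list", n); T_pes <- vector("list", n)
    for (i in frames) {
      pel_pose <- list(FE_deg = script$pelvis$yaw[i],
                       ABAD_deg = script$pelvis$pitch[i],
                       LAR_deg = script$pelvis$roll[i],
                       t_x_mm = script$pelvis$tx[i],
                       t_y_mm = script$pelvis$ty[i],
                       t_z_mm = script$pelvis$tz[i])
      T_pel[[i]] <- compose_pose(jset$pelvis, pel_pose, ident)
      T_fem[[i]] <- compose_pose(jset$hip, script_record(script$hip, i), T_pel[[i]])
      T_cru[[i]] <- compose_pose(jset$knee, script_record(script$knee, i), T_fem[[i]])
      T_pes[[i]] <- compose_pose(jset$ankle, script_record(script$ankle, i), T_cru[[i]])
    }
    sequences[[paste0("pelvis_", side)]] <-
      transform_sequence("pelvis", side, frames, T_pel)
    sequences[[paste0("femur_", side)]] <-
      transform_sequence("femur", side, frames, T_fem)
    sequences[[paste0("crus_", side)]] <-
      transform_sequence("crus", side, frames, T_cru)
    sequences[[paste0("pes_", side)]] <-
      transform_sequence("pes", side, frames, T_pes)
    if (!bp$fused) {
      seg <- limb$segments[[paste0("pes_", side)]]
      med0 <- seg$landmarks$medial
      lat0 <- seg$landmarks$lateral
      ysign <- if (side == "right") 1 else -1
      lm <- t(vapply(frames, function(i) {
        sp <- if (is.null(script$pedal)) 0 else script$pedal$spread_mm[i]
        sk <- if (is.null(script$pedal)) 0 else script$pedal$skew_mm[i]
        med <- med0 + c(sk, -ysign * sp, 0)
        lat <- lat0 + c(-sk, ysign * sp, 0)
        c(apply_transform(T_pes[[i]], med), apply_transform(T_pes[[i]], lat))
      }, numeric(6)))
      landmarks[[side]] <- data.frame(
        frame = frames,
        medial_x = lm[, 1], medial_y = lm[, 2], medial_z = lm[, 3],
        lateral_x = lm[, 4], lateral_y = lm[, 5], lateral_z = lm[, 6])
    }
  }
  list(sequences = sequences, pedal_landmarks = landmarks,
       script = script, ground = ground)
}
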