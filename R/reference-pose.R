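# Reference-pose assembly and whole-chain pose decomposition.
#
# An "ACS set" is a flat named list of acs objects in segment-local
# coordinates: pelvicACSm, hipACSf_R, hipACSf_L, and per side (suffix _R/_L)
# hipACSm, kneeACSf, kneeACSm, ankleACSf, ankleACSm.

side_suffix <- function(side) if (side == "right") "_R" else "_L"

chain_segments <- function(side) {
  s <- if (side == "right") "right" else "left"
  c(pelvis = "pelvis", femur = paste0("femur_", s), crus = paste0("crus_", s),
    pes = paste0("pes_", s))
}

# Rigid transform that registers a local ACS exactly onto a world-frame
# target ACS (origins and axes in complete alignment).
register_acs_transform <- function(target_world, local) {
  R <- target_world$axes %*% t(local$axes)
  rigid_transform(R, target_world$origin - as.vector(R %*% local$origin))
}

require_acs <- function(acs_set, name) {
  a <- acs_set[[name]]
  if (is.null(a)) stop("ACS set is missing '", name, "'", call. = FALSE)
  a
}

#' Assemble the zeroed reference pose of the hindlimb chain
#'
#' Proximal to distal, each segment is placed so that its mobile ACS is
#' exactly registered onto the fixed ACS of its parent: the pelvis onto the
#' ground ACS, the femur's hipACSm onto the pelvis's world-frame hipACSf, the
#' crus's kneeACSm onto the femur's kneeACSf, and the pes's ankleACSm onto
#' the crus's ankleACSf. Decomposing any joint of the result yields six
#' zeros: this is the configuration from which all translations and
#' rotations are measured. The limb is fully collapsed, and bone models are
#' expected to interpenetrate.
#'
#' @param acs_set named list of segment-local [acs()] objects (see above).
#' @param ground a [ground_acs()].
#' @param sides character vector, subset of `c("right", "left")`.
#' @return named list of [rigid_transform()]s: `pelvis`, and per side
#'   `femur_right`/`crus_right`/`pes_right` (resp. `_left`).
#' @export
assemble_reference_pose <- function(acs_set, ground = ground_acs(),
                                    sides = "right") {
  sides <- match.arg(sides, c("right", "left"), several.ok = TRUE)
  out <- list()
  out$pelvis <- register_acs_transform(ground,
                                       require_acs(acs_set, "pelvicACSm"))
  for (side in sides) {
    sfx <- side_suffix(side)
    hip_f_w <- acs_world(require_acs(acs_set, paste0("hipACSf", sfx)),
                         out$pelvis)
    T_femur <- register_acs_transform(hip_f_w,
                                      require_acs(acs_set, paste0("hipACSm", sfx)))
    knee_f_w <- acs_world(require_acs(acs_set, paste0("kneeACSf", sfx)), T_femur)
    T_crus <- register_acs_transform(knee_f_w,
                                     require_acs(acs_set, paste0("kneeACSm", sfx)))
    ankle_f_w <- acs_world(require_acs(acs_set, paste0("ankleACSf", sfx)), T_crus)
    T_pes <- register_acs_transform(ankle_f_w,
                                    require_acs(acs_set, paste0("ankleACSm", sfx)))
    out[[paste0("femur_", side)]] <- T_femur
    out[[paste0("crus_", side)]] <- T_crus
    out[[paste0("pes_", side)]] <- T_pes
  }
  out
}

#' Build the four JCSs of one hindlimb
#'
#' @param acs_set named list of segment-local [acs()] objects.
#' @param ground a [ground_acs()].
#' @param side `"right"` or `"left"`.
#' @return named list of [jcs()] objects: `pelvis`, `hip`, `knee`, `ankle`.
#' @export
limb_jcs <- function(acs_set, ground = ground_acs(), side = "right") {
  side <- match.arg(side, c("right", "left"))
  sfx <- side_suffix(side)
  list(
    pelvis = jcs("pelvis", "midline", ground,
                 require_acs(acs_set, "pelvicACSm")),
    hip = jcs("hip", side, require_acs(acs_set, paste0("hipACSf", sfx)),
              require_acs(acs_set, paste0("hipACSm", sfx))),
    knee = jcs("knee", side, require_acs(acs_set, paste0("kneeACSf", sfx)),
               require_acs(acs_set, paste0("kneeACSm", sfx))),
    ankle = jcs("ankle", side, require_acs(acs_set, paste0("ankleACSf", sfx)),
                require_acs(acs_set, paste0("ankleACSm", sfx))))
}

# Look up the transform of a segment at one frame from a list of
# transform_sequence objects keyed "<segment>_<side>" ("pelvis_right" for
# the midline pelvis by convention).
sequence_transform <- function(sequences, segment, side, frame) {
  key <- paste(segment, side, sep = "_")
  s <- sequences[[key]]
  if (is.null(s) && segment == "pelvis") {
    hit <- grep("^pelvis", names(sequences), value = TRUE)
    if (length(hit) > 0) s <- sequences[[hit[1]]]
  }
  if (is.null(s)) stop("no transform sequence for segment '", key, "'",
                       call. = FALSE)
  i <- match(frame, s$frames)
  if (is.na(i)) stop("segment '", key, "' has no frame ", frame, call. = FALSE)
  s$transforms[[i]]
}

#' Decompose every joint of a hindlimb over a transform sequence
#'
#' Runs [decompose_pose()] at the pelvis pseudo-joint, hip, knee and ankle
#' for every frame. With `pes_mode = "dynamic"`, the ankle's mobile ACS is
#' rebuilt each frame in world coordinates from the tracked outer-metatarsal
#' landmarks ([build_pedal_acs_dynamic()]) instead of using the static
#' segment-fixed ankleACSm; the proximal plane centroid still rides with the
#' pes segment.
#'
#' @param acs_set named list of segment-local [acs()] objects.
#' @param sequences named list of [transform_sequence()] (keys
#'   `"pelvis_right"`, `"femur_right"`, ...).
#' @param ground a [ground_acs()].
#' @param side `"right"` or `"left"`.
#' @param pes_mode `"static"` or `"dynamic"`.
#' @param pedal_landmarks required for dynamic mode: data.frame with columns
#'   `frame, medial_x, medial_y, medial_z, lateral_x, lateral_y, lateral_z`
#'   (world coordinates per frame).
#' @param unwrap if `TRUE`, add `FE_unwrapped_deg` / `LAR_unwrapped_deg`
#'   columns continuous across the +/-180 degree seam (per joint).
#' @return pose-table data.frame, one row per joint per frame.
#' @export
limb_pose_table <- function(acs_set, sequences, ground = ground_acs(),
                            side = "right",
                            pes_mode = c("static", "dynamic"),
                            pedal_landmarks = NULL, unwrap = FALSE) {
  pes_mode <- match.arg(pes_mode)
  side <- match.arg(side, c("right", "left"))
  jset <- limb_jcs(acs_set, ground, side)
  pelvis_key <- grep("^pelvis", names(sequences), value = TRUE)[1]
  if (is.na(pelvis_key)) stop("no pelvis transform sequence", call. = FALSE)
  frames <- sequences[[pelvis_key]]$frames
  if (pes_mode == "dynamic") {
    if (is.null(pedal_landmarks))
      stop("dynamic pes mode needs pedal_landmarks", call. = FALSE)
    need <- c("frame", "medial_x", "medial_y", "medial_z",
              "lateral_x", "lateral_y", "lateral_z")
    if (!all(need %in% names(pedal_landmarks)))
      stop("pedal_landmarks must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
  }
  sfx <- side_suffix(side)
  ident <- rigid_transform()
  rows <- vector("list", 4L * length(frames))
  k <- 0L
  for (fr in frames) {
    T_pelvis <- sequence_transform(sequences, "pelvis", side, fr)
    T_femur <- sequence_transform(sequences, "femur", side, fr)
    T_crus <- sequence_transform(sequences, "crus", side, fr)
    T_pes <- sequence_transform(sequences, "pes", side, fr)
    rows[[k <- k + 1L]] <- decompose_pose(jset$pelvis, ident, T_pelvis, fr)
    rows[[k <- k + 1L]] <- decompose_pose(jset$hip, T_pelvis, T_femur, fr)
    rows[[k <- k + 1L]] <- decompose_pose(jset$knee, T_femur, T_crus, fr)
    if (pes_mode == "static") {
      rows[[k <- k + 1L]] <- decompose_pose(jset$ankle, T_crus, T_pes, fr)
    } else {
      lm <- pedal_landmarks[pedal_landmarks$frame == fr, , drop = FALSE]
      if (nrow(lm) != 1L)
        stop("pedal_landmarks must have exactly one row for frame ", fr,
             call. = FALSE)
      prox_w <- apply_transform(
        T_pes, require_acs(acs_set, paste0("ankleACSm", sfx))$origin)
      acs_dyn <- build_pedal_acs_dynamic(
        prox_w,
        c(lm$medial_x, lm$medial_y, lm$medial_z),
        c(lm$lateral_x, lm$lateral_y, lm$lateral_z), side)
      j_dyn <- jcs("ankle", side,
                   require_acs(acs_set, paste0("ankleACSf", sfx)), acs_dyn)
      rows[[k <- k + 1L]] <- decompose_pose(j_dyn, T_crus, ident, fr)
    }
  }
  tab <- pose_table(rows)
  if (unwrap) {
    tab$FE_unwrapped_deg <- NA_real_
    tab$LAR_unwrapped_deg <- NA_real_
    for (jn in unique(tab$joint)) {
      i <- which(tab$joint == jn)
      i <- i[order(tab$frame[i])]
      tab$FE_unwrapped_deg[i] <- unwrap_deg(tab$FE_deg[i])
      tab$LAR_unwrapped_deg[i] <- unwrap_deg(tab$LAR_deg[i])
    }
  }
  tab
}

#' Export world-frame ACS origins and axes per frame as JSON
#'
#' A rendering hook for external viewers: for every frame, every segment's
#' ACSs are written in world coordinates.
#'
#' @param acs_set named list of segment-local [acs()] objects.
#' @param sequences named list of [transform_sequence()].
#' @param side `"right"` or `"left"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_scene_json <- function(acs_set, sequences, side, path) {
  sfx <- side_suffix(side)
  seg_of <- c(pelvicACSm = "pelvis", hipACSf_R = "pelvis", hipACSf_L = "pelvis")
  local_names <- c("pelvicACSm", paste0("hipACSf", sfx))
  seg_for <- c("pelvis", "pelvis")
  for (nm in c("hipACSm", "kneeACSf")) {
    local_names <- c(local_names, paste0(nm, sfx)); seg_for <- c(seg_for, "femur")
  }
  for (nm in c("kneeACSm", "ankleACSf")) {
    local_names <- c(local_names, paste0(nm, sfx)); seg_for <- c(seg_for, "crus")
  }
  local_names <- c(local_names, paste0("ankleACSm", sfx))
  seg_for <- c(seg_for, "pes")
  pelvis_key <- grep("^pelvis", names(sequences), value = TRUE)[1]
  frames <- sequences[[pelvis_key]]$frames
  scene <- lapply(frames, function(fr) {
    systems <- list()
    for (i in seq_along(local_names)) {
      a <- acs_set[[local_names[i]]]
      if (is.null(a)) next
      tf <- sequence_transform(sequences, seg_for[i], side, fr)
      w <- acs_world(a, tf)
      systems[[local_names[i]]] <- list(origin = w$origin,
                                        X = w$axes[, "X"], Y = w$axes[, "Y"],
                                        Z = w$axes[, "Z"])
    }
    list(frame = fr, acs = systems)
  })
  jsonlite::write_json(scene, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
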