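# Rigid transforms (local -> world) and per-segment transform sequences,
# with the CSV interchange format used for motion data (e.g. XROMM output).

#' Construct a rigid transform
#'
#' Maps segment-local coordinates to world coordinates as
#' `x_world = R %*% x_local + t` (rotation applied before translation).
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (mm).
#' @param tol orthogonality/determinant tolerance.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite 3-vector", call. = FALSE)
  if (!is_rotation_matrix(rotation, tol))
    stop("rotation must be proper orthogonal (det = +1) within ", tol,
         call. = FALSE)
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  e <- euler_zyx(x$R)
  cat(sprintf("rigid_transform: t = (%.3f, %.3f, %.3f) mm, zyx = (%.2f, %.2f, %.2f) deg\n",
              x$t[1], x$t[2], x$t[3], e$rz_deg, e$ry_deg, e$rx_deg))
  invisible(x)
}

#' Apply a rigid transform to points or directions
#'
#' @param tf a [rigid_transform()].
#' @param x 3-vector or n x 3 matrix.
#' @param type `"point"` (rotate + translate) or `"direction"` (rotate only).
#' @return transformed coordinates, same shape as `x`.
#' @export
apply_transform <- function(tf, x, type = c("point", "direction")) {
  type <- match.arg(type)
  if (is.matrix(x)) {
    out <- x %*% t(tf$R)
    if (type == "point") out <- sweep(out, 2, tf$t, "+")
    out
  } else {
    out <- as.vector(tf$R %*% x)
    if (type == "point") out <- out + tf$t
    out
  }
}

compose_transforms <- function(a, b) {
  # (a o b): apply b first, then a
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.vector(-t(tf$R) %*% tf$t))
}

#' Construct a transform sequence for one segment
#'
#' @param segment_name segment label (`"pelvis"`, `"femur"`, `"crus"`, `"pes"`).
#' @param side `"right"` or `"left"`.
#' @param frames integer vector of frame indices, strictly increasing.
#' @param transforms list of [rigid_transform()], one per frame.
#' @return object of class `transform_sequence`.
#' @export
transform_sequence <- function(segment_name, side, frames, transforms) {
  frames <- as.integer(frames)
  if (length(frames) != length(transforms))
    stop("frames and transforms must have equal length", call. = FALSE)
  if (length(frames) > 1 && any(diff(frames) <= 0))
    stop("frame indices must be strictly increasing", call. = FALSE)
  side <- match.arg(side, c("right", "left"))
  for (tf in transforms)
    if (!inherits(tf, "rigid_transform"))
      stop("all transforms must be rigid_transform objects", call. = FALSE)
  structure(list(segment_name = segment_name, side = side,
                 frames = frames, transforms = transforms),
            class = "transform_sequence")
}

#' @export
print.transform_sequence <- function(x, ...) {
  cat("transform_sequence:", x$segment_name, paste0("(", x$side, "),"),
      length(x$frames), "frames\n")
  invisible(x)
}

#' Write transform sequences to CSV
#'
#' One row per segment/side/frame. Rotations are stored as unit quaternions
#' (`qw,qx,qy,qz`, scalar first), which round-trip through text much better
#' than raw matrices. Columns:
#' `segment,side,frame,tx,ty,tz,qw,qx,qy,qz`.
#'
#' @param sequences list of [transform_sequence()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(sequences, path) {
  rows <- lapply(sequences, function(s) {
    q <- t(vapply(s$transforms, function(tf) rot_to_quat(tf$R), numeric(4)))
    tt <- t(vapply(s$transforms, function(tf) tf$t, numeric(3)))
    data.frame(segment = s$segment_name, side = s$side, frame = s$frames,
               tx = tt[, 1], ty = tt[, 2], tz = tt[, 3],
               qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read transform sequences from CSV
#'
#' Accepts the quaternion dialect written by [write_transforms()] and, as an
#' alternative, a 9-element row-major rotation dialect with columns
#' `segment,side,frame,tx,ty,tz,r11,r12,r13,r21,...,r33`.
#'
#' @param path path to CSV.
#' @return named list of [transform_sequence()], names `"<segment>_<side>"`.
#' @export
read_transforms <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "side", "frame", "tx", "ty", "tz")
  if (!all(need %in% names(df)))
    stop("transform CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  has_quat <- all(c("qw", "qx", "qy", "qz") %in% names(df))
  rnames <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  has_mat <- all(rnames %in% names(df))
  if (!has_quat && !has_mat)
    stop("transform CSV needs quaternion (qw..qz) or rotation (r11..r33) columns",
         call. = FALSE)
  key <- paste(df$segment, df$side, sep = "_")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    tfs <- lapply(seq_len(nrow(sub)), function(i) {
      R <- if (has_quat) {
        quat_to_rot(as.numeric(sub[i, c("qw", "qx", "qy", "qz")]))
      } else {
        matrix(as.numeric(sub[i, rnames]), 3, 3, byrow = TRUE)
      }
      # re-orthonormalize against text round-off before validation
      sv <- svd(R)
      R <- sv$u %*% t(sv$v)
      if (det(R) < 0) stop("improper rotation in ", path, call. = FALSE)
      rigid_transform(R, as.numeric(sub[i, c("tx", "ty", "tz")]))
    })
    out[[k]] <- transform_sequence(sub$segment[1], sub$side[1],
                                   sub$frame, tfs)
  }
  out
}
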