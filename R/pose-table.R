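# Joint pose records: the six-DOF output table of the pipeline.

#' Construct a joint pose record
#'
#' @param joint one of `"pelvis"`, `"hip"`, `"knee"`, `"ankle"`.
#' @param side `"right"` or `"left"`.
#' @param frame_index integer frame number.
#' @param FE_deg,ABAD_deg,LAR_deg rotations in degrees (for the pelvis
#'   pseudo-joint these are yaw, pitch and roll respectively).
#' @param t_x_mm,t_y_mm,t_z_mm translations of the mobile-ACS origin from the
#'   fixed-ACS origin, measured along the fixed-ACS axes (mm).
#' @param gimbal_flag `TRUE` when |ABAD| is at 90 degrees within tolerance, in
#'   which case FE and LAR are reported but not individually unique.
#' @return one-row data.frame of class `joint_pose_record`.
#' @export
joint_pose_record <- function(joint, side, frame_index,
                              FE_deg, ABAD_deg, LAR_deg,
                              t_x_mm, t_y_mm, t_z_mm,
                              gimbal_flag = FALSE) {
  joint <- match.arg(joint, c("pelvis", "hip", "knee", "ankle"))
  side <- match.arg(side, c("right", "left"))
  vals <- c(FE_deg, ABAD_deg, LAR_deg, t_x_mm, t_y_mm, t_z_mm)
  if (!all(is.finite(vals))) stop("pose values must be finite", call. = FALSE)
  df <- data.frame(frame = as.integer(frame_index), joint = joint, side = side,
                   FE_deg = FE_deg, ABAD_deg = ABAD_deg, LAR_deg = LAR_deg,
                   t_x_mm = t_x_mm, t_y_mm = t_y_mm, t_z_mm = t_z_mm,
                   gimbal_flag = isTRUE(gimbal_flag))
  class(df) <- c("joint_pose_record", class(df))
  df
}

pose_table_columns <- function() {
  c("frame", "joint", "side", "FE_deg", "ABAD_deg", "LAR_deg",
    "t_x_mm", "t_y_mm", "t_z_mm", "gimbal_flag")
}

#' Bind pose records into a pose table
#'
#' @param records list of [joint_pose_record()] rows (or data.frames with the
#'   same columns).
#' @return data.frame with one row per record.
#' @export
pose_table <- function(records) {
  if (length(records) == 0L) stop("no pose records", call. = FALSE)
  df <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(r)[, pose_table_columns()]
  }))
  rownames(df) <- NULL
  df
}

#' Write a pose table to CSV
#'
#' Numeric fields are written with enough digits to round-trip within 1e-9.
#'
#' @param records a pose table data.frame or list of records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(records, path) {
  df <- if (is.data.frame(records)) records else pose_table(records)
  if (nrow(df) == 0L) stop("no pose records to write", call. = FALSE)
  missing_cols <- setdiff(pose_table_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("pose table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- df[, pose_table_columns()]
  for (col in c("FE_deg", "ABAD_deg", "LAR_deg", "t_x_mm", "t_y_mm", "t_z_mm"))
    out[[col]] <- sprintf("%.15g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pose table from CSV
#'
#' @param path path written by [write_pose_table()].
#' @return data.frame with the standard pose-table columns.
#' @export
read_pose_table <- function(path) {
  if (!file.exists(path)) stop("pose table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(pose_table_columns() %in% names(df)))
    stop("not a pose table: ", path, call. = FALSE)
  df$gimbal_flag <- as.logical(df$gimbal_flag)
  df
}
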