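#' Ventricular CSF compartments
#'
#' Compartment labels used in slice segmentations. Integer codes (for label
#' masks) are the positions in this vector; `0` is background.
#'
#' @return Named integer vector of compartment codes.
#' @export
compartments <- function() {
  c(LATERAL_L = 1L, LATERAL_R = 2L, THIRD = 3L, AQUEDUCT = 4L, FOURTH = 5L,
    EXTRA_AXIAL = 6L)
}

#' Default compartment inclusion policy
#'
#' Lateral (both sides) and third ventricles are included; the cerebral
#' aqueduct, fourth ventricle and extra-axial subarachnoid spaces are
#' excluded, because in coronal neonatal scans only the lateral and third
#' ventricles are consistently captured.
#'
#' @return Character vector of included compartment names.
#' @export
default_inclusion <- function() c("LATERAL_L", "LATERAL_R", "THIRD")

#' Per-compartment area from a label mask
#'
#' Converts an integer label mask of one MR slice into physical areas:
#' `area(compartment) = pixel count x row spacing x column spacing`.
#'
#' @param label_mask integer matrix; values `0` (background) or compartment
#'   codes from [compartments()].
#' @param pixel_spacing numeric length-2, mm per pixel edge `(row, col)`;
#'   a single value is used for both.
#' @return Named numeric vector: area in mm2 for every compartment (zero when
#'   absent from the mask).
#' @export
area_from_mask <- function(label_mask, pixel_spacing) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) {
    stop("pixel spacing must be positive", call. = FALSE)
  }
  comp <- compartments()
  vals <- unique(as.vector(label_mask))
  unknown <- setdiff(vals, c(0L, unname(comp)))
  if (length(unknown)) {
    stop("unknown label value(s) in mask: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  px_area <- pixel_spacing[1] * pixel_spacing[2]
  vapply(comp, function(code) sum(label_mask == code) * px_area, numeric(1))
}

#' One slice-area record table
#'
#' Builds/validates the long table of per-slice segmented areas:
#' one row per (subject, day, slice, compartment).
#'
#' @param subject_id,day,slice_index,compartment,area_mm2,thickness_mm
#'   column vectors (recycled per data.frame rules).
#' @return A validated data.frame of slice-area records.
#' @export
slice_area_records <- function(subject_id, day, slice_index, compartment,
                               area_mm2, thickness_mm) {
  df <- data.frame(subject_id = as.character(subject_id),
                   day = as.integer(day),
                   slice_index = as.integer(slice_index),
                   compartment = as.character(compartment),
                   area_mm2 = as.numeric(area_mm2),
                   thickness_mm = as.numeric(thickness_mm),
                   stringsAsFactors = FALSE)
  validate_slice_records(df)
}

validate_slice_records <- function(df) {
  bad <- setdiff(df$compartment, names(compartments()))
  if (length(bad)) {
    stop("unknown compartment(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$area_mm2 < 0)) stop("areas must be non-negative", call. = FALSE)
  if (any(df$thickness_mm <= 0)) {
    stop("slice thickness must be positive", call. = FALSE)
  }
  key <- paste(df$subject_id, df$day, df$slice_index, df$compartment)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, day, slice, compartment) records",
         call. = FALSE)
  }
  df
}

#' Ventricular volume from slice areas (Cavalieri estimator)
#'
#' Computes one scan's ventricular CSF volume as the sum of
#' `area x slice thickness` over every slice record whose compartment is in
#' the inclusion set, converted from mm3 to mL. This is the Cavalieri
#' estimator; for a single slice it reduces to area times thickness.
#'
#' @param records slice-area data.frame as from [slice_area_records()]; all
#'   rows must share one `subject_id` and `day`.
#' @param inclusion character vector of compartments to include; defaults to
#'   [default_inclusion()].
#' @param allow_mixed_thickness records within one scan are expected to share
#'   a slice thickness; set `TRUE` to override the consistency check.
#' @return A list of class `volume_measurement`: `subject_id`, `day`,
#'   `volume_mL`, `n_slices_included`, `compartments_included`.
#' @export
volume_from_areas <- function(records, inclusion = default_inclusion(),
                              allow_mixed_thickness = FALSE) {
  if (nrow(records) == 0L) stop("empty record list", call. = FALSE)
  records <- validate_slice_records(records)
  if (length(unique(records$subject_id)) != 1L ||
      length(unique(records$day)) != 1L) {
    stop("all records must share one subject_id and day", call. = FALSE)
  }
  if (!allow_mixed_thickness &&
      length(unique(records$thickness_mm)) != 1L) {
    stop("mixed slice thickness within one scan; pass ",
         "allow_mixed_thickness = TRUE to override", call. = FALSE)
  }
  bad <- setdiff(inclusion, names(compartments()))
  if (length(bad)) {
    stop("unknown compartment(s) in inclusion set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  inc <- records[records$compartment %in% inclusion, , drop = FALSE]
  vol_mm3 <- sum(inc$area_mm2 * inc$thickness_mm)
  structure(list(subject_id = records$subject_id[1], day = records$day[1],
                 volume_mL = vol_mm3 / 1000,
                 n_slices_included = length(unique(inc$slice_index)),
                 compartments_included = sort(unique(inclusion))),
            class = "volume_measurement")
}

#' @export
print.volume_measurement <- function(x, ...) {
  cat(sprintf("subject %s day %d: %.6g mL over %d slice(s) [%s]\n",
              x$subject_id, x$day, x$volume_mL, x$n_slices_included,
              paste(x$compartments_included, collapse = ", ")))
  invisible(x)
}

#' Assemble group-wise longitudinal volume trajectories
#'
#' Joins per-scan volume measurements to a subject-to-group table and returns
#' the long-format trajectory table used by the trend and comparison
#' analyses. Missing visits stay absent: a subject scanned on three of four
#' days contributes three rows, never an imputed fourth (scans lost to early
#' death or scanner downtime are simply not rows).
#'
#' @param measurements a list of `volume_measurement` objects (from
#'   [volume_from_areas()]) or a data.frame with columns `subject_id`, `day`,
#'   `volume_mL`.
#' @param groups data.frame with columns `subject_id`, `group` mapping every
#'   subject to exactly one group.
#' @return data.frame `(group, subject_id, day, volume_mL)`, ordered by
#'   group, subject, day.
#' @export
build_trajectories <- function(measurements, groups) {
  if (is.data.frame(measurements)) {
    df <- measurements[, c("subject_id", "day", "volume_mL")]
  } else {
    df <- do.call(rbind, lapply(measurements, function(m) {
      data.frame(subject_id = m$subject_id, day = m$day,
                 volume_mL = m$volume_mL, stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(groups$subject_id)) {
    stop("a subject is mapped to more than one group", call. = FALSE)
  }
  unmapped <- setdiff(df$subject_id, groups$subject_id)
  if (length(unmapped)) {
    stop("subject(s) without a group mapping: ",
         paste(unique(unmapped), collapse = ", "), call. = FALSE)
  }
  out <- merge(df, groups[, c("subject_id", "group")], by = "subject_id")
  out <- out[order(out$group, out$subject_id, out$day), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("group", "subject_id", "day", "volume_mL")]
}

#' Per-group, per-day mean volumes
#'
#' @param trajectories long table from [build_trajectories()].
#' @return data.frame `(group, day, mean_volume_mL, n)`.
#' @export
group_day_means <- function(trajectories) {
  agg <- aggregate(volume_mL ~ group + day, data = trajectories, FUN = mean)
  n <- aggregate(volume_mL ~ group + day, data = trajectories, FUN = length)
  out <- merge(agg, n, by = c("group", "day"),
               suffixes = c("", "_n"))
  names(out) <- c("group", "day", "mean_volume_mL", "n")
  out[order(out$group, out$day), , drop = FALSE]
}
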