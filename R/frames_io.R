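#' @useDynLib dynapet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats sd setNames
#' @importFrom tibble tibble as_tibble
NULL

abort_dynapet <- function(msg, class = "dynapet_error") {
  abort(msg, class = class)
}

#' Build a frame schedule from explicit start and end times
#'
#' A frame schedule is the temporal grid of a dynamic PET acquisition: an
#' ordered set of contiguous, non-overlapping, half-open intervals
#' `[start_s, end_s)` in seconds. Frame mid-times and durations are derived.
#'
#' @param start_s,end_s Numeric vectors of frame start/end times in seconds.
#' @return A tibble of class `frame_schedule` with columns `start_s`, `end_s`,
#'   `mid_s`, `dur_s`, one row per frame.
#' @examples
#' frame_schedule(c(0, 5, 10), c(5, 10, 20))
#' @export
frame_schedule <- function(start_s, end_s) {
  if (length(start_s) == 0L || length(start_s) != length(end_s)) {
    abort_dynapet("`start_s` and `end_s` must be non-empty and equal length.")
  }
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    abort_dynapet("Frame times must be finite.")
  }
  if (start_s[1] < 0) abort_dynapet("First frame must start at time >= 0.")
  if (any(end_s <= start_s)) abort_dynapet("Every frame needs end_s > start_s.")
  n <- length(start_s)
  if (n > 1L && any(abs(start_s[-1] - end_s[-n]) > 1e-9)) {
    abort_dynapet("Frames must be contiguous: each start must equal the previous end.")
  }
  out <- tibble(
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    mid_s = (as.numeric(start_s) + as.numeric(end_s)) / 2,
    dur_s = as.numeric(end_s) - as.numeric(start_s)
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Parse a compact frame-schedule specification
#'
#' Dynamic PET protocols are usually written as a run-length list such as
#' "12 x 5 s, 6 x 10 s, ...". This expands such a specification into a
#' contiguous [frame_schedule()] starting at 0 s.
#'
#' @param spec A data frame with columns `count` (integer, >= 1) and
#'   `duration_s` (seconds, > 0), or a list of `c(count, duration_s)` pairs.
#' @return A [frame_schedule()] with `sum(count)` frames.
#' @examples
#' # a 60-min FDG protocol: 39 frames, 3600 s total
#' sched <- parse_schedule_spec(tibble::tibble(
#'   count = c(12, 6, 3, 2, 6, 10),
#'   duration_s = c(5, 10, 20, 30, 60, 300)
#' ))
#' nrow(sched)
#' @export
parse_schedule_spec <- function(spec) {
  if (is.list(spec) && !is.data.frame(spec)) {
    spec <- do.call(rbind, lapply(spec, function(p) {
      data.frame(count = p[[1]], duration_s = p[[2]])
    }))
  }
  if (!is.data.frame(spec) || nrow(spec) == 0L) {
    abort_dynapet("Schedule spec must be a non-empty data frame or list of pairs.")
  }
  if (!all(c("count", "duration_s") %in% names(spec))) {
    abort_dynapet("Schedule spec needs `count` and `duration_s` columns.")
  }
  count <- spec$count
  dur <- spec$duration_s
  if (any(count < 1) || any(count != round(count))) {
    abort_dynapet("Frame counts must be positive integers.")
  }
  if (any(dur <= 0)) abort_dynapet("Frame durations must be positive.")
  durs <- rep(dur, times = count)
  ends <- cumsum(durs)
  frame_schedule(start_s = c(0, ends[-length(ends)]), end_s = ends)
}

total_duration <- function(schedule) {
  schedule$end_s[nrow(schedule)] - schedule$start_s[1]
}

#' Counts-calibration record
#'
#' Links activity concentration (kBq/ml) to expected detected counts through
#' an effective `sensitivity` (counts per kBq * s, i.e. per unit of
#' concentration x volume x time) and a `dose_fraction` emulating a reduced
#' injected dose. The product concentration x voxel volume x frame duration x
#' sensitivity x dose_fraction gives the expected counts of a voxel-frame.
#'
#' @param sensitivity Expected counts per (kBq/ml * ml * s). Must be > 0.
#' @param dose_fraction Unitless dose scaling in (0, 1].
#' @return A list of class `counts_calibration`.
#' @export
counts_calibration <- function(sensitivity = 60, dose_fraction = 1) {
  if (!is.finite(sensitivity) || sensitivity <= 0) {
    abort_dynapet("`sensitivity` must be a positive number.")
  }
  if (!is.finite(dose_fraction) || dose_fraction <= 0 || dose_fraction > 1) {
    abort_dynapet("`dose_fraction` must lie in (0, 1].")
  }
  structure(list(sensitivity = sensitivity, dose_fraction = dose_fraction),
            class = "counts_calibration")
}

#' 4D dynamic-image container
#'
#' Binds a 4D activity-concentration array (kBq/ml, indexed x, y, z, frame)
#' to its voxel geometry, [frame_schedule()] and [counts_calibration()].
#'
#' @param voxels 4D numeric array; fourth dimension must match the schedule.
#' @param voxel_size_mm Length-3 positive numeric, voxel edge lengths in mm.
#' @param schedule A [frame_schedule()].
#' @param calibration A [counts_calibration()].
#' @return A list of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, voxel_size_mm, schedule,
                          calibration = counts_calibration()) {
  if (length(dim(voxels)) != 4L) abort_dynapet("`voxels` must be a 4D array.")
  if (!inherits(schedule, "frame_schedule")) {
    abort_dynapet("`schedule` must be a frame_schedule.")
  }
  if (dim(voxels)[4] != nrow(schedule)) {
    abort_dynapet("Fourth dimension of `voxels` must equal the schedule frame count.")
  }
  if (any(!is.finite(voxels))) abort_dynapet("Activity values must be finite.")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    abort_dynapet("`voxel_size_mm` must be three positive numbers.")
  }
  stopifnot(inherits(calibration, "counts_calibration"))
  structure(
    list(voxels = voxels, voxel_size_mm = voxel_size_mm,
         schedule = schedule, calibration = calibration),
    class = "dynamic_image"
  )
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<dynamic_image> %d x %d x %d voxels (%.1f x %.1f x %.1f mm), %d frames over %.0f s\n",
    d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    d[4], total_duration(x$schedule)
  ))
  invisible(x)
}

voxel_volume_ml <- function(image) prod(image$voxel_size_mm) / 1000

#' Subject metadata for SUV scaling
#'
#' @param injected_dose_MBq Injected activity in MBq.
#' @param weight_kg Body weight in kg.
#' @param tracer Tracer label, e.g. `"FDG"`.
#' @param half_life_s Radionuclide half-life in seconds (F-18 default).
#' @return A list of class `subject_meta`.
#' @export
subject_meta <- function(injected_dose_MBq, weight_kg, tracer = "FDG",
                         half_life_s = 6586.2) {
  vals <- c(injected_dose_MBq, weight_kg, half_life_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_dynapet("Dose, weight and half-life must all be positive.")
  }
  structure(list(injected_dose_MBq = injected_dose_MBq, weight_kg = weight_kg,
                 tracer = tracer, half_life_s = half_life_s),
            class = "subject_meta")
}

new_tac <- function(mid_s, mean, sd, units) {
  out <- tibble(mid_s = as.numeric(mid_s), mean = as.numeric(mean),
                sd = as.numeric(sd), units = units)
  if (any(out$sd < -1e-12, na.rm = TRUE)) abort_dynapet("TAC sd must be >= 0.")
  class(out) <- c("pet_tac", class(out))
  out
}

#' Extract a region time-activity curve (TAC)
#'
#' Computes the per-frame mean and spatial standard deviation of voxel values
#' inside a mask. The sd is the population SD over mask voxels (spatial
#' spread, not temporal variability).
#'
#' @param image A [dynamic_image()].
#' @param mask 3D logical array matching the image's spatial dimensions.
#' @return A tibble of class `pet_tac` with columns `mid_s`, `mean`, `sd`,
#'   `units`.
#' @export
roi_extract <- function(image, mask) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$voxels)
  md <- dim(mask) %||% length(mask)
  if (!identical(as.integer(md), as.integer(d[1:3]))) {
    abort_dynapet("Mask shape must match the image's spatial dimensions.")
  }
  mask <- as.logical(mask)
  n <- sum(mask)
  if (n == 0L) abort_dynapet("Mask is empty.")
  flat <- matrix(image$voxels, nrow = prod(d[1:3]), ncol = d[4])
  vals <- flat[which(mask), , drop = FALSE]
  mu <- colMeans(vals)
  # population SD over mask voxels
  sdv <- sqrt(colMeans(sweep(vals, 2, mu)^2))
  new_tac(image$schedule$mid_s, mu, sdv, "kBq/ml")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold a volume of interest at a fraction of its maximum
#'
#' Returns the voxels inside `parent_mask` whose value is at least
#' `fraction` times the maximum value inside the parent. Used e.g. to define
#' a lesion as 60% of the maximum voxel value within a larger VOI, which is
#' robust for heterogeneous lesions with a necrotic core.
#'
#' @param image3d 3D numeric array (a static summary image; see
#'   [static_summary()]).
#' @param parent_mask 3D logical array, non-empty.
#' @param fraction Threshold fraction in (0, 1]. Default 0.6.
#' @return 3D logical array.
#' @export
threshold_voi <- function(image3d, parent_mask, fraction = 0.6) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    abort_dynapet("`fraction` must lie in (0, 1].")
  }
  parent_mask <- array(as.logical(parent_mask), dim = dim(image3d))
  if (!sum(parent_mask)) abort_dynapet("Parent mask is empty.")
  mx <- max(image3d[parent_mask])
  if (mx <= 0) abort_dynapet("Parent region is all zero; cannot threshold.")
  out <- parent_mask & (image3d >= fraction * mx)
  out
}

#' Time-weighted static summary of a dynamic image
#'
#' Duration-weighted mean of all frames whose start time is at or after
#' `from_s`. This is the default static image on which fractional-maximum
#' VOI thresholds are applied (late frames, where uptake patterns are
#' established).
#'
#' @param image A [dynamic_image()].
#' @param from_s Earliest frame start to include, seconds (default 600).
#' @return 3D numeric array.
#' @export
static_summary <- function(image, from_s = 600) {
  keep <- which(image$schedule$start_s >= from_s - 1e-9)
  if (!length(keep)) abort_dynapet("No frames start at or after `from_s`.")
  w <- image$schedule$dur_s[keep]
  d <- dim(image$voxels)
  acc <- array(0, d[1:3])
  for (i in seq_along(keep)) acc <- acc + image$voxels[, , , keep[i]] * w[i]
  acc / sum(w)
}

#' Convert a TAC from kBq/ml to SUV
#'
#' SUV = concentration / (injected dose / body weight), with dose in kBq and
#' weight in g (1 g of tissue taken as 1 ml).
#'
#' @param tac A `pet_tac` in kBq/ml.
#' @param meta A [subject_meta()].
#' @return The TAC rescaled to SUV (`units = "SUV"`); `sd` is scaled too.
#' @export
suv_scale <- function(tac, meta) {
  stopifnot(inherits(meta, "subject_meta"))
  if (!all(tac$units %in% "kBq/ml")) {
    abort_dynapet("`suv_scale` expects a TAC in kBq/ml.")
  }
  f <- (meta$weight_kg * 1000) / (meta$injected_dose_MBq * 1000)
  new_tac(tac$mid_s, tac$mean * f, tac$sd * f, "SUV")
}

# ---- file I/O -------------------------------------------------------------

#' Write / read a dynamic image as NIfTI plus a JSON frame-schedule sidecar
#'
#' The image is stored as NIfTI-1 (`<path>.nii.gz`) and the schedule as
#' `<path>.json` with the layout `{"frames": [[start_s, end_s], ...],
#' "calibration": {...}}`. The round trip is lossless for voxel values
#' (float64), geometry, schedule and calibration.
#'
#' @param image A [dynamic_image()].
#' @param path Path stem (extensions are appended).
#' @return `write_dynamic_image` returns `path` invisibly;
#'   `read_dynamic_image` returns a [dynamic_image()].
#' @export
write_dynamic_image <- function(image, path) {
  stopifnot(inherits(image, "dynamic_image"))
  nii <- RNifti::asNifti(
    structure(image$voxels, pixdim = c(image$voxel_size_mm, 1)),
    datatype = "double")
  RNifti::writeNifti(nii, paste0(path, ".nii.gz"))
  side <- list(
    frames = mapply(c, image$schedule$start_s, image$schedule$end_s,
                    SIMPLIFY = FALSE),
    calibration = list(sensitivity = image$calibration$sensitivity,
                       dose_fraction = image$calibration$dose_fraction)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(path) {
  nii <- RNifti::readNifti(paste0(path, ".nii.gz"))
  vox <- as.array(nii)
  vox <- array(as.numeric(vox), dim(vox))
  if (length(dim(vox)) == 3L) dim(vox) <- c(dim(vox), 1L)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fr <- side$frames
  if (is.list(fr)) fr <- do.call(rbind, fr)
  if (nrow(fr) != dim(vox)[4]) {
    abort_dynapet("Sidecar frame count does not match the image's fourth dimension.")
  }
  cal <- counts_calibration(side$calibration$sensitivity,
                            side$calibration$dose_fraction)
  dynamic_image(vox, RNifti::pixdim(nii)[1:3],
                frame_schedule(fr[, 1], fr[, 2]), cal)
}

#' Write / read a TAC as CSV
#'
#' Columns `mid_s, mean, sd, units`.
#'
#' @param tac A `pet_tac`.
#' @param path CSV file path.
#' @export
write_tac <- function(tac, path) {
  utils::write.csv(as.data.frame(tac)[c("mid_s", "mean", "sd", "units")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_tac(df$mid_s, df$mean, df$sd, df$units)
}

#' Write / read a 3D mask or map as NIfTI
#' @param vol 3D array.
#' @param voxel_size_mm Length-3 voxel size.
#' @param path File path (`.nii.gz`).
#' @export
write_volume <- function(vol, voxel_size_mm, path) {
  nii <- RNifti::asNifti(structure(vol * 1, pixdim = voxel_size_mm),
                         datatype = "double")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  v <- as.array(RNifti::readNifti(path))
  array(as.numeric(v), dim(v))
}
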