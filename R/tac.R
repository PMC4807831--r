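#' Select the first-frame threshold ROI
#'
#' The region-of-interest rule for point-source studies: all voxels whose
#' value in the reference frame is strictly greater than
#' `threshold_fraction` times that frame's maximum. The maximum voxel
#' always qualifies. The same mask is then applied to every frame to read
#' out the time-activity curve.
#'
#' @param series A `dynamic_image_series`.
#' @param threshold_fraction Fraction of the reference-frame maximum, in
#'   (0, 1). Default 0.5 (the 50% isocontour).
#' @param reference_frame Frame used to define the mask (default 1, the
#'   first frame).
#'
#' @return An object of class `roi_mask`: logical 3D `mask` plus
#'   `threshold_fraction`, `reference_frame` and `voxel_count`.
#' @export
select_roi <- function(series, threshold_fraction = 0.5,
                       reference_frame = 1L) {
  stopifnot(inherits(series, "dynamic_image_series"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("`threshold_fraction` must be in (0, 1)", call. = FALSE)
  }
  nf <- dim(series$values)[4]
  if (reference_frame < 1 || reference_frame > nf) {
    stop(sprintf("reference frame %d outside 1..%d", reference_frame, nf),
         call. = FALSE)
  }
  vol <- series$values[, , , reference_frame]
  peak <- max(vol)
  if (peak <= 0) {
    stop("reference frame contains no signal (all-zero): no source to segment",
         call. = FALSE)
  }
  mask <- vol > threshold_fraction * peak
  # strict > can exclude the peak itself only through ties at the
  # threshold, which cannot happen for the maximum; keep the guarantee
  # explicit anyway
  mask[which.max(vol)] <- TRUE
  structure(
    list(mask = mask,
         threshold_fraction = threshold_fraction,
         reference_frame = as.integer(reference_frame),
         voxel_count = sum(mask)),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels (> %.0f%% of frame-%d max)\n",
              x$voxel_count, 100 * x$threshold_fraction, x$reference_frame))
  invisible(x)
}

#' Extract a time-activity curve through an ROI mask
#'
#' Sums the series over the mask in every frame and converts to a
#' frame-averaged activity rate (counts / sensitivity / duration when the
#' series holds counts). With `decay_correct = TRUE` each frame is divided
#' by the frame-averaged physical decay factor, so the remaining time
#' dependence is purely biological; frames already corrected upstream are
#' left untouched.
#'
#' @param series A `dynamic_image_series`.
#' @param roi An `roi_mask` from [select_roi()], aligned to the series.
#' @param isotope An [isotope_spec()] for the decay correction.
#' @param decay_correct Divide out physical decay? Default `TRUE`.
#'
#' @return A tibble of class `tac` with columns `frame`, `t_start`,
#'   `t_mid`, `duration`, `value` (Bq, ROI sum) and attributes
#'   `decay_corrected`, `units` and `provenance`.
#' @export
extract_tac <- function(series, roi, isotope = isotope_11c(),
                        decay_correct = TRUE) {
  stopifnot(inherits(series, "dynamic_image_series"),
            inherits(roi, "roi_mask"))
  d <- dim(series$values)
  if (!identical(dim(roi$mask), d[1:3])) {
    stop(sprintf("ROI grid %s does not match series grid %s",
                 paste(dim(roi$mask), collapse = "x"),
                 paste(d[1:3], collapse = "x")), call. = FALSE)
  }
  ft <- series$frame_timing
  vals <- vapply(seq_len(d[4]),
                 function(f) sum(series$values[, , , f][roi$mask]),
                 numeric(1))
  if (identical(series$units, "counts")) {
    vals <- vals / (series$sensitivity * ft$duration)
  }
  corrected <- isTRUE(series$decay_corrected)
  if (decay_correct && !corrected) {
    stopifnot(inherits(isotope, "isotope_spec"))
    vals <- vals / frame_mean_exp(isotope$lambda, ft$t_start, ft$duration)
    corrected <- TRUE
  }
  new_tac(
    tibble::tibble(frame = ft$frame, t_start = ft$t_start, t_mid = ft$t_mid,
                   duration = ft$duration, value = vals),
    decay_corrected = corrected,
    provenance = list(
      roi_voxels = roi$voxel_count,
      roi_threshold = roi$threshold_fraction,
      roi_reference_frame = roi$reference_frame,
      roi_statistic = "sum",
      series_units = series$units,
      series_noise = isTRUE(series$noise),
      series_seed = series$seed
    )
  )
}

new_tac <- function(data, decay_corrected, provenance = list()) {
  req <- c("frame", "t_start", "t_mid", "duration", "value")
  stopifnot(all(req %in% names(data)))
  if (is.unsorted(data$t_mid, strictly = TRUE)) {
    stop("TAC frame times must be strictly increasing", call. = FALSE)
  }
  if (any(data$value < 0)) stop("TAC values must be >= 0", call. = FALSE)
  out <- tibble::as_tibble(data[req])
  attr(out, "decay_corrected") <- isTRUE(decay_corrected)
  attr(out, "units") <- "Bq"
  attr(out, "provenance") <- provenance
  class(out) <- c("tac", class(out))
  out
}

#' Build a TAC from a frame table
#'
#' Constructor for time-activity curves supplied as plain tables (the
#' alternative input path when no image series is available). Requires
#' frame start times, durations and values; midpoints are derived.
#'
#' @param data Data frame with columns `t_start`, `duration`, `value`
#'   (seconds, seconds, activity). An optional `frame` column is kept;
#'   otherwise frames are numbered in order.
#' @param decay_corrected Whether the values have already been corrected
#'   for physical decay.
#'
#' @return A `tac` tibble.
#' @export
#' @examples
#' as_tac(data.frame(t_start = c(0, 30, 60), duration = 30,
#'                   value = c(100, 90, 81)))
as_tac <- function(data, decay_corrected = TRUE) {
  req <- c("t_start", "duration", "value")
  if (!all(req %in% names(data))) {
    stop("`data` needs columns t_start, duration, value", call. = FALSE)
  }
  if (!"frame" %in% names(data)) data$frame <- seq_len(nrow(data))
  data$t_mid <- data$t_start + data$duration / 2
  new_tac(data, decay_corrected = decay_corrected,
          provenance = list(source = "table"))
}

#' Is a TAC decay-corrected?
#'
#' @param tac A `tac` tibble from [extract_tac()] or [read_tac()].
#' @return Logical flag recorded at extraction time.
#' @export
is_decay_corrected <- function(tac) isTRUE(attr(tac, "decay_corrected"))

fwhm_1d <- function(profile, step) {
  ipk <- which.max(profile)
  pk <- profile[ipk]
  half <- pk / 2
  if (ipk == 1L || ipk == length(profile)) {
    stop("profile peak lies on the grid boundary; FWHM undefined",
         call. = FALSE)
  }
  left <- NA_real_
  for (i in seq(ipk, 2L)) {
    if (profile[i - 1] <= half && profile[i] > half) {
      frac <- (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      left <- (i - 1) + frac # in voxel index units (centres at 1..n)
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk, length(profile) - 1L)) {
    if (profile[i + 1] <= half && profile[i] > half) {
      frac <- (profile[i] - half) / (profile[i] - profile[i + 1])
      right <- i + frac
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("half-maximum crossing not found inside the grid", call. = FALSE)
  }
  (right - left) * step
}

#' Measure the point-source FWHM of one frame
#'
#' Full width at half maximum of the activity spot: 1D profiles through the
#' peak voxel along each grid axis, with linear interpolation at half
#' maximum, averaged over the three axes.
#'
#' @param series A `dynamic_image_series`.
#' @param frame Frame index to measure (default 1).
#'
#' @return FWHM in mm (mean over axes) with attribute `per_axis` (named
#'   length-3 vector).
#' @export
measure_fwhm <- function(series, frame = 1L) {
  stopifnot(inherits(series, "dynamic_image_series"))
  d <- dim(series$values)
  if (frame < 1 || frame > d[4]) {
    stop(sprintf("frame %d outside 1..%d", frame, d[4]), call. = FALSE)
  }
  vol <- series$values[, , , frame]
  if (max(vol) <= 0) stop("frame has no positive peak", call. = FALSE)
  pk <- arrayInd(which.max(vol), d[1:3])[1, ]
  per_axis <- c(
    x = fwhm_1d(vol[, pk[2], pk[3]], series$voxel_size[1]),
    y = fwhm_1d(vol[pk[1], , pk[3]], series$voxel_size[2]),
    z = fwhm_1d(vol[pk[1], pk[2], ], series$voxel_size[3])
  )
  structure(mean(per_axis), per_axis = per_axis)
}
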