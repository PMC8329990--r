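# Per-vesicle copy-number estimation and condition summaries.

#' Estimate cargo copy numbers from calibrated spot intensities
#'
#' Divides each retained spot's background-subtracted peak intensity by the
#' calibrated single-fluorophore unit intensity.  Estimates are real-valued
#' (not rounded): the readout is a ratio of intensities, and downstream
#' summaries bin it.  Estimates below `detection_limit` are flagged
#' `below_detection` and excluded from condition summaries — vesicle samples
#' are heterogeneous and less pure than the reference fluorophore, so a
#' stringent limit of 3 molecules guards against counting noise as cargo.
#'
#' @param spots Spot-call data frame; only `status == "retained"` rows are
#'   converted.
#' @param calibration A `unit_calibration` from [calibrate_unit_intensity()].
#' @param detection_limit Copy-number detection limit (default 3).
#' @return A data frame with `spot_id`, `copy_number_est`, `below_detection`.
#' @examples
#' cal <- structure(list(mean_unit_peak_adu = 100, cv_unit = 0,
#'                       n_accepted = 50, n_reference = 50),
#'                  class = "unit_calibration")
#' spots <- data.frame(spot_id = "s1", peak_intensity_adu = 500,
#'                     status = "retained")
#' estimate_copy_numbers(spots, cal)
#' @export
estimate_copy_numbers <- function(spots, calibration, detection_limit = 3.0) {
  stopifnot(inherits(calibration, "unit_calibration"))
  if (!is.finite(calibration$mean_unit_peak_adu) ||
      calibration$mean_unit_peak_adu <= 0) {
    stop("invalid calibration: unit intensity must be positive",
         call. = FALSE)
  }
  check_scalar(detection_limit, "detection_limit", lower = 0)
  keep <- spots$status == "retained"
  est <- spots$peak_intensity_adu[keep] / calibration$mean_unit_peak_adu
  data.frame(spot_id = spots$spot_id[keep],
             copy_number_est = est,
             below_detection = est < detection_limit,
             stringsAsFactors = FALSE)
}

#' Summarize copy numbers for one condition
#'
#' Mean copy number over above-detection records plus a binned histogram of
#' the copy-number distribution.
#'
#' @param records Data frame from [estimate_copy_numbers()].
#' @param label Condition label.
#' @param bin_width Histogram bin width in copies (default 10).
#' @return A list of class `condition_summary` with `condition_label`,
#'   `n_retained` (records converted), `n_above_detection`,
#'   `mean_copy_number` (over above-detection records), and `histogram`
#'   (data frame with `bin_lower`, `bin_upper`, `count` over above-detection
#'   records).
#' @export
summarize_condition <- function(records, label, bin_width = 10) {
  check_scalar(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  vals <- records$copy_number_est[!records$below_detection]
  if (length(vals) == 0L) {
    stop("empty condition: no records above the detection limit",
         call. = FALSE)
  }
  breaks <- seq(0, (floor(max(vals) / bin_width) + 1) * bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(vals, breaks, right = FALSE)))
  structure(list(
    condition_label = label,
    n_retained = nrow(records),
    n_above_detection = length(vals),
    mean_copy_number = mean(vals),
    histogram = data.frame(bin_lower = head(breaks, -1),
                           bin_upper = breaks[-1],
                           count = counts)
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    "Condition '%s': %d spots, %d above detection, mean %.1f copies/vesicle\n",
    x$condition_label, x$n_retained, x$n_above_detection,
    x$mean_copy_number))
  invisible(x)
}

#' Run the full copy-number pipeline on one vesicle stack
#'
#' Convenience wrapper chaining the canonical analysis: average the first
#' `k` frames, center-crop, estimate the background, detect and area-filter
#' spots, check the density QC, and convert retained spots to copy numbers.
#'
#' @param stack An `ev_image_stack` of a vesicle field.
#' @param calibration A `unit_calibration`.
#' @param k Frames to average (default 4).
#' @param crop_side_um Center-crop side in um (default 65); `NULL` skips the
#'   crop (e.g. when the simulated field is already small).
#' @param threshold_factor,area_min_um2,area_max_um2,detection_limit,max_per_10um2
#'   Pipeline parameters, see the stage functions.
#' @return A list with `image`, `background_adu`, `spots`, `qc`, `records`.
#' @export
quantify_stack <- function(stack, calibration, k = 4, crop_side_um = 65,
                           threshold_factor = 2.0, area_min_um2 = 0.1,
                           area_max_um2 = 10.0, detection_limit = 3.0,
                           max_per_10um2 = 1) {
  img <- average_frames(stack, k = k)
  if (!is.null(crop_side_um)) img <- crop_center(img, crop_side_um)
  bg <- estimate_background(img)
  spots <- detect_spots(img, bg)
  spots <- filter_spots(spots, area_min_um2, area_max_um2)
  area <- prod(dim(img$data)) * img$pixel_size_um^2
  qc <- qc_density(spots, area, max_per_10um2)
  records <- estimate_copy_numbers(spots, calibration, detection_limit)
  list(image = img, background_adu = bg, spots = spots, qc = qc,
       records = records)
}
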