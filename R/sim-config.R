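#' Imaging configuration for synthetic widefield image stacks
#'
#' Bundles the camera and optics parameters used by [simulate_reference_field()]
#' and [simulate_ev_field()].  Defaults emulate a 60x/1.49 NA widefield setup
#' imaging GFP: a 0.108 um camera pixel and an effective point-spread-function
#' (PSF) sigma of 0.15 um (the nominal diffraction sigma inflated for frame
#' averaging and slight defocus, so that bright diffraction-limited spots
#' occupy more than 0.1 um^2 after thresholding).
#'
#' The camera model is: photon shot noise as Poisson counts on
#' (background + signal), additive Gaussian read noise, plus a constant
#' baseline offset.  Pixel values are clipped at zero, so rendered frames are
#' non-negative everywhere.
#'
#' @param width_px,height_px Field size in pixels (positive integers).
#' @param pixel_size_um Physical pixel size in um/pixel (> 0).
#' @param psf_sigma_um Isotropic Gaussian PSF sigma in um (> 0).
#' @param background_adu Mean diffuse background level in ADU (>= 0), on top
#'   of the baseline; sampled with shot noise.
#' @param read_noise_adu Gaussian read-noise standard deviation in ADU (>= 0).
#' @param baseline_adu Constant camera offset in ADU (>= 0).
#' @param n_frames Number of frames in the stack (>= 1).
#' @param frame_interval_s Time between consecutive frames in seconds (> 0).
#' @param shot_noise Apply Poisson shot noise to (background + signal)
#'   (default TRUE).  Disabling it (together with `read_noise_adu = 0`)
#'   produces exactly rendered, noiseless frames for worked examples and
#'   linearity checks.
#' @param seed Integer seed; identical configuration + seed gives bit-identical
#'   simulated output.
#' @return An object of class `sim_image_config`.
#' @examples
#' cfg <- sim_image_config(width_px = 128, height_px = 128, seed = 1)
#' cfg
#' @export
sim_image_config <- function(width_px = 602L, height_px = 602L,
                             pixel_size_um = 0.108, psf_sigma_um = 0.15,
                             background_adu = 20, read_noise_adu = 2,
                             baseline_adu = 20, n_frames = 4L,
                             frame_interval_s = 0.1, shot_noise = TRUE,
                             seed = 1L) {
  check_scalar(width_px, "width_px", lower = 1, integerish = TRUE)
  check_scalar(height_px, "height_px", lower = 1, integerish = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  check_scalar(psf_sigma_um, "psf_sigma_um", lower = 0, strict_lower = TRUE)
  check_scalar(background_adu, "background_adu", lower = 0)
  check_scalar(read_noise_adu, "read_noise_adu", lower = 0)
  check_scalar(baseline_adu, "baseline_adu", lower = 0)
  check_scalar(n_frames, "n_frames", lower = 1, integerish = TRUE)
  check_scalar(frame_interval_s, "frame_interval_s", lower = 0,
               strict_lower = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  stopifnot(is.logical(shot_noise), length(shot_noise) == 1L)
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um,
    background_adu = background_adu, read_noise_adu = read_noise_adu,
    baseline_adu = baseline_adu, n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s, shot_noise = shot_noise,
    seed = as.integer(seed)
  ), class = "sim_image_config")
}

#' @export
print.sim_image_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic imaging configuration\n  field: %d x %d px (%.1f x %.1f um), pixel %.3f um\n  PSF sigma: %.3f um\n  camera: background %g ADU, read noise %g ADU, baseline %g ADU\n  frames: %d @ %.3g s, seed %d\n",
    x$width_px, x$height_px, x$width_px * x$pixel_size_um,
    x$height_px * x$pixel_size_um, x$pixel_size_um, x$psf_sigma_um,
    x$background_adu, x$read_noise_adu, x$baseline_adu,
    x$n_frames, x$frame_interval_s, x$seed))
  invisible(x)
}

#' Construct an image stack
#'
#' Container for a multi-frame grayscale acquisition: an ordered list of 2D
#' intensity matrices (ADU) sharing dimensions, the physical pixel size, and
#' the frame interval.
#'
#' @param frames List of numeric matrices (rows = y, cols = x), all the same
#'   dimension, all non-negative.
#' @param pixel_size_um Physical pixel size in um/pixel.
#' @param acquisition_interval_s Time between frames in seconds.
#' @return An object of class `ev_image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, acquisition_interval_s = 0.1) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (!all(dims == dims[, 1])) {
    stop("all frames must share dimensions", call. = FALSE)
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    stop("frame intensities must be non-negative", call. = FALSE)
  }
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 acquisition_interval_s = acquisition_interval_s),
            class = "ev_image_stack")
}

#' @export
print.ev_image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "Image stack: %d frame(s), %d x %d px, pixel %.3f um, interval %.3g s\n",
    length(x$frames), d[2], d[1], x$pixel_size_um, x$acquisition_interval_s))
  invisible(x)
}
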