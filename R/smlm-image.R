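# Image-level preprocessing for the copy-number pipeline: frame averaging,
# center cropping, robust background estimation.

#' Single 2D image with physical pixel size
#'
#' @param data Numeric matrix (rows = y, cols = x), non-negative ADU.
#' @param pixel_size_um Physical pixel size in um/pixel (> 0).
#' @return An object of class `ev_image`.
#' @export
ev_image <- function(data, pixel_size_um) {
  if (!is.matrix(data) || !is.numeric(data) || length(data) == 0L) {
    stop("'data' must be a non-empty numeric matrix", call. = FALSE)
  }
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  structure(list(data = data, pixel_size_um = pixel_size_um),
            class = "ev_image")
}

#' @export
print.ev_image <- function(x, ...) {
  cat(sprintf("Image: %d x %d px (%.1f x %.1f um), pixel %.3f um\n",
              ncol(x$data), nrow(x$data),
              ncol(x$data) * x$pixel_size_um, nrow(x$data) * x$pixel_size_um,
              x$pixel_size_um))
  invisible(x)
}

as_ev_image <- function(image) {
  if (inherits(image, "ev_image")) return(image)
  stop("expected an 'ev_image' (see ev_image() or average_frames())",
       call. = FALSE)
}

#' Average consecutive frames of an image stack
#'
#' Signal-to-background enhancement: the pixel-wise arithmetic mean of the
#' first `k` frames.  Averaging k frames reduces the background noise variance
#' by a factor of k while leaving the (static) signal unchanged.
#'
#' @param stack An `ev_image_stack` (see [image_stack()]).
#' @param k Number of consecutive frames to average (default 4).
#' @return An [ev_image()] carrying the stack's pixel size.
#' @examples
#' stk <- image_stack(list(matrix(2, 4, 4), matrix(4, 4, 4)), 0.108)
#' average_frames(stk, k = 2)$data[1, 1]  # 3
#' @export
average_frames <- function(stack, k = 4) {
  stopifnot(inherits(stack, "ev_image_stack"))
  check_scalar(k, "k", lower = 1, integerish = TRUE)
  if (length(stack$frames) < k) {
    stop(sprintf("insufficient frames: stack has %d, need %d",
                 length(stack$frames), k), call. = FALSE)
  }
  acc <- Reduce(`+`, stack$frames[seq_len(k)]) / k
  ev_image(acc, stack$pixel_size_um)
}

#' Crop a centered square region of an image
#'
#' Restricts analysis to the center of the field, where illumination is
#' flattest (vignetting affects the periphery).  The physical side is
#' converted to whole pixels by flooring; the crop is centered by pixel index.
#'
#' @param image An [ev_image()].
#' @param side_um Physical side of the square crop in um (default 65).
#' @return The cropped [ev_image()].
#' @export
crop_center <- function(image, side_um = 65.0) {
  image <- as_ev_image(image)
  check_scalar(side_um, "side_um", lower = 0, strict_lower = TRUE)
  h <- nrow(image$data)
  w <- ncol(image$data)
  side_px <- floor(side_um / image$pixel_size_um)
  if (side_px > h || side_px > w) {
    stop("field too small for the requested crop", call. = FALSE)
  }
  r0 <- floor((h - side_px) / 2)
  c0 <- floor((w - side_px) / 2)
  ev_image(image$data[(r0 + 1):(r0 + side_px), (c0 + 1):(c0 + side_px),
                      drop = FALSE],
           image$pixel_size_um)
}

#' Robust scalar background estimate
#'
#' Median of all pixels, refined once by re-taking the median over pixels
#' below (median + 3 x MAD).  The refinement guards against fields where
#' bright spots contaminate the first-pass median.
#'
#' @param image An [ev_image()] or numeric matrix.
#' @return Background level in ADU (scalar).
#' @export
estimate_background <- function(image) {
  img <- if (inherits(image, "ev_image")) image$data else image
  if (!is.numeric(img) || length(img) == 0L) {
    stop("image must be non-empty numeric", call. = FALSE)
  }
  med <- median(img)
  cut <- med + 3 * mad(img)
  keep <- img[img <= cut]
  if (length(keep) == 0L) return(med)
  median(keep)
}
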