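# Thresholded spot detection, area filtering and density QC.

# Label connected components of a logical mask.  Vertices are mask pixels;
# edges join neighbouring mask pixels under 8- or 4-connectivity.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4, 8))
  idx <- which(mask)
  if (length(idx) == 0L) {
    return(list(n = 0L, membership = integer(0), pixel_index = integer(0)))
  }
  h <- nrow(mask)
  w <- ncol(mask)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0)
  to <- integer(0)
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    rr <- seq_len(h - dr)
    cc <- if (dc >= 0) seq_len(w - dc) else seq(1 - dc, w)
    sub <- mask[rr, cc, drop = FALSE] & mask[rr + dr, cc + dc, drop = FALSE]
    k <- which(sub)
    if (length(k) == 0L) next
    nr <- length(rr)
    r1 <- rr[((k - 1L) %% nr) + 1L]
    c1 <- cc[((k - 1L) %/% nr) + 1L]
    from <- c(from, (c1 - 1L) * h + r1)
    to <- c(to, (c1 + dc - 1L) * h + r1 + dr)
  }
  vid_from <- match(from, idx)
  vid_to <- match(to, idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(vid_from) > 0L) {
    g <- igraph::add_edges(g, rbind(vid_from, vid_to))
  }
  comp <- igraph::components(g)
  list(n = comp$no, membership = as.integer(comp$membership),
       pixel_index = idx)
}

#' Detect diffraction-limited spots by background thresholding
#'
#' Binarizes the image at strictly greater than
#' `threshold_factor * background_adu` (the "> 2-fold background" rule),
#' labels connected components, and summarizes each component as a spot call:
#' intensity-weighted centroid, physical area, background-subtracted peak and
#' integrated intensity.
#'
#' @param image An [ev_image()] (typically the 4-frame average, center-cropped).
#' @param background_adu Scalar background level in ADU (> 0), e.g. from
#'   [estimate_background()].
#' @param threshold_factor Multiple of background defining the mask (> 1,
#'   default 2); pixels must exceed it strictly.
#' @param connectivity Pixel connectivity for component labelling, 8 (default)
#'   or 4.
#' @param keep_pixels If `TRUE`, attach each spot's pixel index set as the
#'   `pixels` attribute (used for diagnostics and oracle checks).
#' @return A data frame of spot calls with columns `spot_id`,
#'   `centroid_x_um`, `centroid_y_um`, `area_um2`, `n_pixels`,
#'   `peak_intensity_adu`, `integrated_intensity_adu`, `peak_row`, `peak_col`
#'   and `status` (initialized to `"retained"`; see [filter_spots()]).
#' @export
detect_spots <- function(image, background_adu, threshold_factor = 2.0,
                         connectivity = 8, keep_pixels = FALSE) {
  image <- as_ev_image(image)
  if (!is.numeric(background_adu) || length(background_adu) != 1L ||
      !is.finite(background_adu) || background_adu <= 0) {
    stop("invalid background: must be a positive scalar", call. = FALSE)
  }
  check_scalar(threshold_factor, "threshold_factor", lower = 1,
               strict_lower = TRUE)
  img <- image$data
  px <- image$pixel_size_um
  mask <- img > threshold_factor * background_adu
  lab <- label_components(mask, connectivity = connectivity)
  empty <- data.frame(spot_id = character(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), area_um2 = numeric(0),
                      n_pixels = integer(0), peak_intensity_adu = numeric(0),
                      integrated_intensity_adu = numeric(0),
                      peak_row = integer(0), peak_col = integer(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (lab$n == 0L) {
    if (keep_pixels) attr(empty, "pixels") <- list()
    return(empty)
  }
  h <- nrow(img)
  rows <- ((lab$pixel_index - 1L) %% h) + 1L
  cols <- ((lab$pixel_index - 1L) %/% h) + 1L
  vals <- img[lab$pixel_index] - background_adu  # > 0 on the mask
  grp <- lab$membership
  grp_f <- factor(grp, levels = seq_len(lab$n))  # keep numeric group order

  n_pixels <- as.integer(tabulate(grp, lab$n))
  sum_w <- as.numeric(tapply(vals, grp_f, sum))
  # intensity-weighted centroid at pixel centers
  cx <- as.numeric(tapply(vals * (cols - 0.5), grp_f, sum)) / sum_w * px
  cy <- as.numeric(tapply(vals * (rows - 0.5), grp_f, sum)) / sum_w * px
  peak <- as.numeric(tapply(vals, grp_f, max))
  # location of the peak pixel, first occurrence on ties (column-major order)
  ord <- order(grp, -vals, lab$pixel_index)
  first <- ord[!duplicated(grp[ord])]
  peak_row <- rows[first][order(grp[first])]
  peak_col <- cols[first][order(grp[first])]

  out <- data.frame(
    spot_id = sprintf("spot_%04d", seq_len(lab$n)),
    centroid_x_um = cx, centroid_y_um = cy,
    area_um2 = n_pixels * px^2, n_pixels = n_pixels,
    peak_intensity_adu = pmax(peak, 0),
    integrated_intensity_adu = pmax(sum_w, 0),
    peak_row = peak_row, peak_col = peak_col,
    status = "retained", stringsAsFactors = FALSE)
  if (keep_pixels) {
    attr(out, "pixels") <- split(lab$pixel_index, grp)
  }
  out
}

#' Annotate spot calls with the area filter
#'
#' Spots with area below `area_min_um2` are flagged `removed_small` (noise),
#' above `area_max_um2` flagged `removed_large` (aggregates); the closed
#' interval `[area_min_um2, area_max_um2]` is `retained`.  No rows are
#' deleted, so |detected| = |retained| + |removed_small| + |removed_large|.
#'
#' @param spots Spot-call data frame from [detect_spots()].
#' @param area_min_um2,area_max_um2 Area bounds in um^2 (defaults 0.1 and 10).
#' @return The spot-call data frame with `status` updated.
#' @export
filter_spots <- function(spots, area_min_um2 = 0.1, area_max_um2 = 10.0) {
  check_scalar(area_min_um2, "area_min_um2", lower = 0, strict_lower = TRUE)
  check_scalar(area_max_um2, "area_max_um2", lower = 0, strict_lower = TRUE)
  if (area_min_um2 >= area_max_um2) {
    stop("'area_min_um2' must be < 'area_max_um2'", call. = FALSE)
  }
  status <- rep("retained", nrow(spots))
  status[spots$area_um2 < area_min_um2] <- "removed_small"
  status[spots$area_um2 > area_max_um2] <- "removed_large"
  spots$status <- status
  spots
}

#' Density quality control
#'
#' The copy-number pipeline assumes spatially resolved single vesicles; fields
#' denser than `max_per_10um2` spots per 10 um^2 risk particle overlap and
#' are rejected.
#'
#' @param spots Spot-call data frame (only `status == "retained"` rows count).
#' @param analyzed_area_um2 Physical area of the analyzed region in um^2 (> 0).
#' @param max_per_10um2 Density limit per 10 um^2 (default 1); the field
#'   passes iff density is strictly below the limit.
#' @return A list with `pass` (logical), `density_per_um2`, `n_retained` and
#'   `analyzed_area_um2`.
#' @export
qc_density <- function(spots, analyzed_area_um2, max_per_10um2 = 1) {
  check_scalar(analyzed_area_um2, "analyzed_area_um2", lower = 0,
               strict_lower = TRUE)
  check_scalar(max_per_10um2, "max_per_10um2", lower = 0, strict_lower = TRUE)
  n <- sum(spots$status == "retained")
  dens <- n / analyzed_area_um2
  list(pass = dens < max_per_10um2 / 10, density_per_um2 = dens,
       n_retained = n, analyzed_area_um2 = analyzed_area_um2)
}
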