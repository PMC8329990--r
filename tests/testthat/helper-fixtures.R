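# Shared fixtures built in code: noiseless imaging configurations, pixel
# center grids, and synthetic calibration inputs.

# Noiseless camera: exact rendering, no shot or read noise.
noiseless_config <- function(width_px = 256, height_px = 256,
                             background_adu = 40, n_frames = 1, seed = 1) {
  sim_image_config(width_px = width_px, height_px = height_px,
                   background_adu = background_adu, read_noise_adu = 0,
                   baseline_adu = 0, n_frames = n_frames,
                   shot_noise = FALSE, seed = seed)
}

# Positions pinned to pixel centers on a regular grid (spacing in pixels),
# so rendered peak amplitudes are exact.
grid_positions <- function(n, config, spacing_px = 24, offset_px = 12) {
  per_row <- floor((config$width_px - offset_px) / spacing_px)
  stopifnot(per_row >= 1)
  i <- seq_len(n) - 1
  col <- offset_px + (i %% per_row) * spacing_px
  row <- offset_px + (i %/% per_row) * spacing_px
  stopifnot(all(row < config$height_px))
  data.frame(x_um = (col - 0.5) * config$pixel_size_um,
             y_um = (row - 0.5) * config$pixel_size_um)
}

# A unit calibration built from synthetic noiseless single-step reference
# spots with the given peak intensities.
make_calibration <- function(peaks, n_frames = 12) {
  n <- length(peaks)
  ids <- sprintf("cal_%03d", seq_len(n))
  spots <- data.frame(spot_id = ids, peak_intensity_adu = peaks,
                      status = "retained", stringsAsFactors = FALSE)
  traces <- lapply(seq_len(n), function(i) {
    bleach_trace(ids[i], c(rep(peaks[i], n_frames / 2),
                           rep(0, n_frames / 2)))
  })
  calibrate_unit_intensity(spots, traces, min_accepted = min(30, n))
}
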