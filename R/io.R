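# File interfaces: multi-page 16-bit TIFF stacks, CSV event tables, YAML
# run configuration.

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are stored as unsigned 16-bit ADU (values are rounded and
#' clipped to 0..65535).
#'
#' @param stack An `ev_image_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ev_image_stack"))
  pages <- lapply(stack$frames, function(f) {
    pmin(pmax(round(f), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file path.
#' @param pixel_size_um Physical pixel size (not stored in plain TIFF).
#' @param acquisition_interval_s Frame interval in seconds.
#' @return An `ev_image_stack` with intensities on the 0..65535 ADU scale.
#' @export
read_image_stack <- function(path, pixel_size_um,
                             acquisition_interval_s = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) round(p * 65535))
  image_stack(frames, pixel_size_um, acquisition_interval_s)
}

#' Write / read a flow or chip event table as CSV
#'
#' @param events Event data frame.
#' @param path CSV file path.
#' @return `path` invisibly (write) or the event data frame (read).
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a YAML run configuration
#'
#' @param path YAML file path.
#' @param config Named list of parameters.
#' @return The configuration list (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
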