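# Capture-chip quantification: size windowing, percent GFP+ colocalization,
# per-spot MFI, and isotype background handling.

#' Restrict chip events to the vesicle sizing window
#'
#' Retains events with diameter in the closed window `[min_nm, max_nm]`
#' (default 50-200 nm, the instrument's vesicle sizing thresholds).  When no
#' diameter column is present the operation is the identity, with a warning.
#'
#' @param events Per-spot event data frame (optionally with `diameter_nm`).
#' @param min_nm,max_nm Window bounds in nm, inclusive.
#' @return The filtered event data frame.
#' @export
size_window_filter <- function(events, min_nm = 50, max_nm = 200) {
  check_scalar(min_nm, "min_nm", lower = 0)
  check_scalar(max_nm, "max_nm", lower = min_nm, strict_lower = TRUE)
  if (is.null(events$diameter_nm)) {
    warning("no 'diameter_nm' column: size window not applied")
    return(events)
  }
  events[events$diameter_nm >= min_nm & events$diameter_nm <= max_nm, ,
         drop = FALSE]
}

#' Percent GFP-positive vesicles on one capture spot
#'
#' percent = 100 x (CF555-positive events) / (CF647-positive events): the
#' GFP-labelled fraction of the captured, tetraspanin-labelled population.
#' The literal ratio is used by default, so more CF555+ than CF647+ events
#' yields a value above 100 (reported and flagged rather than clipped);
#' `colocalized_only = TRUE` instead counts only events positive in *both*
#' channels in the numerator.
#'
#' Positivity gates are absolute intensity thresholds; the defaults (15 ADU)
#' sit well above the simulated label-free fluorescence background.
#'
#' @param readout Event data frame for one capture spot (columns `cf647_adu`,
#'   `cf555_adu`, optionally `capture_antibody`).
#' @param cf647_gate,cf555_gate Positivity thresholds in ADU (strictly-above
#'   rule).
#' @param colocalized_only Count only CF555+ AND CF647+ events in the
#'   numerator (default FALSE, the literal formula).
#' @return An object of class `chip_result`: `capture_antibody`,
#'   `n_events`, `n_cf647_pos`, `n_cf555_pos`, `percent_gfp_pos`,
#'   `mfi_cf555`, `over_100` flag.
#' @examples
#' ro <- data.frame(cf647_adu = rep(100, 200),
#'                  cf555_adu = rep(c(100, 0), c(50, 150)))
#' percent_colocalized(ro)$percent_gfp_pos  # 25
#' @export
percent_colocalized <- function(readout, cf647_gate = 15, cf555_gate = 15,
                                colocalized_only = FALSE) {
  check_scalar(cf647_gate, "cf647_gate", lower = 0)
  check_scalar(cf555_gate, "cf555_gate", lower = 0)
  pos647 <- readout$cf647_adu > cf647_gate
  pos555 <- readout$cf555_adu > cf555_gate
  if (colocalized_only) pos555 <- pos555 & pos647
  n647 <- sum(pos647)
  if (n647 == 0L) {
    stop("no captured vesicles: zero CF647-positive events", call. = FALSE)
  }
  n555 <- sum(pos555)
  pct <- 100 * n555 / n647
  structure(list(
    capture_antibody = if (!is.null(readout$capture_antibody) &&
                           nrow(readout) > 0)
      readout$capture_antibody[1] else NA_character_,
    n_events = nrow(readout),
    n_cf647_pos = n647,
    n_cf555_pos = n555,
    percent_gfp_pos = pct,
    mfi_cf555 = mean(readout$cf555_adu),
    over_100 = pct > 100
  ), class = "chip_result")
}

#' @export
print.chip_result <- function(x, ...) {
  cat(sprintf(
    "Chip spot %s: %d events, %d CF647+, %d CF555+, %.1f%% GFP+%s, CF555 MFI %.1f\n",
    x$capture_antibody, x$n_events, x$n_cf647_pos, x$n_cf555_pos,
    x$percent_gfp_pos, if (x$over_100) " (over 100, flagged)" else "",
    x$mfi_cf555))
  invisible(x)
}

#' Mean fluorescence intensity of a capture spot
#'
#' Arithmetic mean of the chosen channel over all events on the spot (the
#' whole captured population, positive or not).
#'
#' @param readout Event data frame for one capture spot.
#' @param channel `"cf555"` (default) or `"cf647"`.
#' @return Mean intensity (ADU).
#' @export
spot_mfi <- function(readout, channel = c("cf555", "cf647")) {
  channel <- match.arg(channel)
  col <- paste0(channel, "_adu")
  x <- readout[[col]]
  if (is.null(x) || length(x) == 0L) {
    stop("empty spot: no events to average", call. = FALSE)
  }
  mean(x)
}

#' Isotype-control background handling
#'
#' Uses the event count on the IgG isotype spot as the nonspecific-binding
#' background: per-spot corrected count = max(0, spot count - IgG count), and
#' a contamination flag is raised when the IgG count exceeds
#' `flag_fraction` (default 10%) of any tetraspanin spot's count.
#'
#' @param sample_readouts Named list of event data frames for the tetraspanin
#'   spots.
#' @param igg_readout Event data frame for the IgG spot.
#' @param flag_fraction Contamination flag threshold (default 0.1).
#' @return A list with `counts` (raw per-spot counts), `igg_count`,
#'   `corrected_counts`, `background_flag`.
#' @export
isotype_background <- function(sample_readouts, igg_readout,
                               flag_fraction = 0.1) {
  if (is.null(igg_readout)) stop("IgG readout is required", call. = FALSE)
  check_probability(flag_fraction, "flag_fraction")
  counts <- vapply(sample_readouts, nrow, integer(1))
  n_igg <- nrow(igg_readout)
  list(counts = counts,
       igg_count = n_igg,
       corrected_counts = pmax(counts - n_igg, 0),
       background_flag = any(n_igg > flag_fraction * counts))
}
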