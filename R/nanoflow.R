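# Nanoflow-cytometry quantification: bead-based size and concentration
# calibration, blank subtraction, control gating, percent-positive / MFI,
# and dye-based purity.

#' Fit a size standard curve from bead events
#'
#' Identifies as many SSC modes as calibration diameters by 1D k-means on the
#' SSC channel, initialized at evenly spaced SSC quantiles (deterministic),
#' and anchors one knot per mode at (median mode SSC, bead diameter), paired
#' in ascending order.  Between knots the curve interpolates monotonically on
#' log-log axes (sub-wavelength silica scatters as a strong power of
#' diameter, so log SSC is close to linear in log diameter); beyond the knots
#' it extrapolates linearly on log-log axes with the boundary chord slope.
#'
#' @param bead_events Data frame with an `ssc_adu` column (e.g. from
#'   [simulate_flow_events()] with `bead_mode = "four_modal"`).
#' @param bead_diameters_nm Ordered calibration diameters; default the
#'   four-modal silica cocktail 68, 91, 113, 155 nm.
#' @param interpolation `"monotone-loglog"` (default) or `"linear"`
#'   (piecewise-linear on natural axes).
#' @return An object of class `ev_size_curve` with `knots` (data frame
#'   `ssc_adu`, `diameter_nm`) and `interpolation`.
#' @export
fit_size_curve <- function(bead_events,
                           bead_diameters_nm = c(68, 91, 113, 155),
                           interpolation = c("monotone-loglog", "linear")) {
  interpolation <- match.arg(interpolation)
  ssc <- bead_events$ssc_adu
  if (is.null(ssc) || length(ssc) < 2 * length(bead_diameters_nm)) {
    stop("too few bead events to identify modes", call. = FALSE)
  }
  diam <- sort(bead_diameters_nm)
  k <- length(diam)
  if (k < 2) stop("need at least two calibration diameters", call. = FALSE)
  init <- quantile(ssc, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  if (anyDuplicated(init)) {
    stop("degenerate bead data: SSC modes are not strictly increasing",
         call. = FALSE)
  }
  km <- kmeans(ssc, centers = matrix(init, ncol = 1))
  mode_ssc <- sort(as.numeric(tapply(ssc, km$cluster, median)))
  if (any(diff(mode_ssc) <= 0) || anyDuplicated(mode_ssc)) {
    stop("degenerate bead data: SSC modes are not strictly increasing",
         call. = FALSE)
  }
  structure(list(knots = data.frame(ssc_adu = mode_ssc, diameter_nm = diam),
                 interpolation = interpolation),
            class = "ev_size_curve")
}

#' Construct a size standard curve from explicit knots
#'
#' @param ssc_adu,diameter_nm Knot coordinates, strictly increasing in both.
#' @inheritParams fit_size_curve
#' @return An `ev_size_curve`.
#' @export
size_curve <- function(ssc_adu, diameter_nm,
                       interpolation = c("monotone-loglog", "linear")) {
  interpolation <- match.arg(interpolation)
  ord <- order(ssc_adu)
  ssc_adu <- ssc_adu[ord]
  diameter_nm <- diameter_nm[ord]
  if (length(ssc_adu) < 2 || any(diff(ssc_adu) <= 0) ||
      any(diff(diameter_nm) <= 0)) {
    stop("knots must be >= 2 and strictly increasing in both coordinates",
         call. = FALSE)
  }
  structure(list(knots = data.frame(ssc_adu = ssc_adu,
                                    diameter_nm = diameter_nm),
                 interpolation = interpolation),
            class = "ev_size_curve")
}

#' @export
print.ev_size_curve <- function(x, ...) {
  cat(sprintf("Size standard curve (%s), %d knots:\n", x$interpolation,
              nrow(x$knots)))
  print(x$knots, row.names = FALSE)
  invisible(x)
}

#' Evaluate a size standard curve at SSC intensities
#'
#' Queries exactly at a knot's SSC return that knot's diameter exactly.
#' Queries beyond the calibrated range are linearly extrapolated (on the
#' curve's axes) when `extrapolate = TRUE`, otherwise returned as `NA`.
#'
#' @param object An `ev_size_curve`.
#' @param ssc_adu Numeric vector of SSC intensities (> 0).
#' @param extrapolate Allow evaluation outside the knot range (default TRUE).
#' @param ... Unused.
#' @return Numeric vector of diameters in nm.
#' @export
predict.ev_size_curve <- function(object, ssc_adu, extrapolate = TRUE, ...) {
  kn <- object$knots
  n <- nrow(kn)
  out <- rep(NA_real_, length(ssc_adu))
  if (object$interpolation == "monotone-loglog") {
    lx <- log(kn$ssc_adu)
    ly <- log(kn$diameter_nm)
    inner <- if (n >= 3) {
      f <- splinefun(lx, ly, method = "hyman")
      function(z) exp(f(log(z)))
    } else {
      function(z) {
        exp(ly[1] + (ly[2] - ly[1]) * (log(z) - lx[1]) / (lx[2] - lx[1]))
      }
    }
    lo_slope <- (ly[2] - ly[1]) / (lx[2] - lx[1])
    hi_slope <- (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
    below <- function(z) exp(ly[1] + lo_slope * (log(z) - lx[1]))
    above <- function(z) exp(ly[n] + hi_slope * (log(z) - lx[n]))
  } else {
    inner <- function(z) {
      stats::approx(kn$ssc_adu, kn$diameter_nm, xout = z)$y
    }
    lo_slope <- (kn$diameter_nm[2] - kn$diameter_nm[1]) /
      (kn$ssc_adu[2] - kn$ssc_adu[1])
    hi_slope <- (kn$diameter_nm[n] - kn$diameter_nm[n - 1]) /
      (kn$ssc_adu[n] - kn$ssc_adu[n - 1])
    below <- function(z) kn$diameter_nm[1] + lo_slope * (z - kn$ssc_adu[1])
    above <- function(z) kn$diameter_nm[n] + hi_slope * (z - kn$ssc_adu[n])
  }
  at_knot <- match(ssc_adu, kn$ssc_adu)
  hit <- !is.na(at_knot)
  out[hit] <- kn$diameter_nm[at_knot[hit]]
  lo <- !hit & ssc_adu < kn$ssc_adu[1]
  hi <- !hit & ssc_adu > kn$ssc_adu[n]
  mid <- !hit & !lo & !hi
  if (any(mid)) out[mid] <- inner(ssc_adu[mid])
  if (extrapolate) {
    if (any(lo)) out[lo] <- below(ssc_adu[lo])
    if (any(hi)) out[hi] <- above(ssc_adu[hi])
  }
  out
}

#' Assign diameters to events via a size standard curve
#'
#' @param events Data frame with `ssc_adu` (and optionally `event_id`).
#' @param curve An `ev_size_curve`.
#' @param extrapolate If `FALSE`, events outside the calibrated SSC range are
#'   flagged `below_range`/`above_range` and get `NA` diameters instead of
#'   being silently extrapolated.
#' @return A list with `diameters` (data frame: `event_id`, `ssc_adu`,
#'   `diameter_nm`, `below_range`, `above_range`) and `summary` (list with
#'   `n`, `mean_nm`, `sd_nm`, `median_nm`, or `defined = FALSE` for an empty
#'   table).
#' @export
apply_size_curve <- function(events, curve, extrapolate = TRUE) {
  stopifnot(inherits(curve, "ev_size_curve"))
  ssc <- events$ssc_adu
  id <- if (!is.null(events$event_id)) events$event_id
        else sprintf("evt_%06d", seq_along(ssc))
  if (length(ssc) == 0L) {
    return(list(diameters = data.frame(event_id = character(0),
                                       ssc_adu = numeric(0),
                                       diameter_nm = numeric(0),
                                       below_range = logical(0),
                                       above_range = logical(0)),
                summary = list(defined = FALSE, n = 0L)))
  }
  d <- predict(curve, ssc, extrapolate = extrapolate)
  below <- ssc < min(curve$knots$ssc_adu)
  above <- ssc > max(curve$knots$ssc_adu)
  ok <- !is.na(d)
  list(
    diameters = data.frame(event_id = id, ssc_adu = ssc, diameter_nm = d,
                           below_range = below, above_range = above,
                           stringsAsFactors = FALSE),
    summary = list(defined = any(ok), n = sum(ok),
                   mean_nm = mean(d[ok]), sd_nm = sd(d[ok]),
                   median_nm = median(d[ok]))
  )
}

#' Concentration calibration from a counting standard
#'
#' The instrument's event rate is proportional to particle concentration;
#' a bead standard of known concentration fixes the proportionality.
#'
#' @param bead_events_per_min Event rate of the bead standard (> 0).
#' @param bead_known_concentration Known bead concentration, particles/ml.
#' @return An object of class `concentration_calibration`.
#' @export
calibrate_concentration <- function(bead_events_per_min,
                                    bead_known_concentration) {
  if (!is.numeric(bead_events_per_min) || length(bead_events_per_min) != 1 ||
      !is.finite(bead_events_per_min) || bead_events_per_min <= 0) {
    stop("invalid standard: bead event rate must be positive", call. = FALSE)
  }
  check_scalar(bead_known_concentration, "bead_known_concentration",
               lower = 0, strict_lower = TRUE)
  structure(list(
    particles_per_ml_per_event_rate =
      bead_known_concentration / bead_events_per_min,
    bead_known_concentration = bead_known_concentration,
    bead_event_rate = bead_events_per_min
  ), class = "concentration_calibration")
}

#' @export
print.concentration_calibration <- function(x, ...) {
  cat(sprintf(
    "Concentration calibration: %.3g particles/ml per event/min (standard %.3g /ml at %.0f events/min)\n",
    x$particles_per_ml_per_event_rate, x$bead_known_concentration,
    x$bead_event_rate))
  invisible(x)
}

#' Estimate sample concentration from its event rate
#'
#' sample concentration = known bead concentration x (sample rate / bead
#' rate) x dilution factor.
#'
#' @param calibration A `concentration_calibration`.
#' @param sample_events_per_min Sample event rate (>= 0).
#' @param dilution_factor Pre-measurement dilution of the sample (default 1).
#' @return Particles/ml in the undiluted sample.
#' @export
estimate_concentration <- function(calibration, sample_events_per_min,
                                   dilution_factor = 1) {
  stopifnot(inherits(calibration, "concentration_calibration"))
  check_scalar(sample_events_per_min, "sample_events_per_min", lower = 0)
  check_scalar(dilution_factor, "dilution_factor", lower = 0,
               strict_lower = TRUE)
  calibration$particles_per_ml_per_event_rate * sample_events_per_min *
    dilution_factor
}

#' Subtract blank (buffer-only) counts from sample counts
#'
#' Element-wise difference clipped at zero; bins must match.
#'
#' @param sample_counts,blank_counts Numeric vectors with identical length
#'   (and names, when named).
#' @return Corrected counts.
#' @export
subtract_blank <- function(sample_counts, blank_counts) {
  if (length(sample_counts) != length(blank_counts)) {
    stop("binning mismatch between sample and blank", call. = FALSE)
  }
  if (!is.null(names(sample_counts)) && !is.null(names(blank_counts)) &&
      !identical(names(sample_counts), names(blank_counts))) {
    stop("binning mismatch between sample and blank", call. = FALSE)
  }
  pmax(sample_counts - blank_counts, 0)
}

flow_channel_column <- function(channel) {
  switch(channel, green = "fl_green_adu", red = "fl_red_adu",
         stop("channel must be 'green' or 'red'", call. = FALSE))
}

#' Set a fluorescence gate from a negative control
#'
#' The threshold is an upper quantile (default 99.5%) of the control sample's
#' channel distribution, so that at most ~0.5% of true negatives fall above
#' the gate.  Events at exactly the threshold count as negative (the
#' strictly-above rule).
#'
#' @param control_events Data frame of control events (needs the channel
#'   column); at least 200 events.
#' @param channel `"green"` or `"red"`.
#' @param quantile Quantile defining the threshold (default 0.995).
#' @param control_id Optional identifier recorded as provenance.
#' @return An object of class `ev_gate` with `channel`, `threshold_adu`,
#'   `quantile`, `control_id`, `n_control`.
#' @export
set_gate <- function(control_events, channel = c("green", "red"),
                     quantile = 0.995, control_id = NULL) {
  channel <- match.arg(channel)
  check_probability(quantile, "quantile")
  x <- control_events[[flow_channel_column(channel)]]
  if (is.null(x) || length(x) < 200L) {
    stop("control underpowered: need at least 200 control events",
         call. = FALSE)
  }
  thr <- as.numeric(stats::quantile(x, probs = quantile, names = FALSE))
  structure(list(channel = channel, threshold_adu = thr, quantile = quantile,
                 control_id = control_id, n_control = length(x)),
            class = "ev_gate")
}

#' @export
print.ev_gate <- function(x, ...) {
  cat(sprintf(
    "Gate on %s channel: threshold %.2f ADU (%.1f%% quantile of %d control events%s)\n",
    x$channel, x$threshold_adu, 100 * x$quantile, x$n_control,
    if (is.null(x$control_id)) "" else paste0(", control ", x$control_id)))
  invisible(x)
}

#' Percent-positive and mean fluorescence intensity against a gate
#'
#' Percent positive = 100 x (events strictly above the threshold) / total.
#' `mfi_all` is the mean channel intensity over *all* events (the total
#' vesicle population, positive or not); `mfi_positive` is the mean over
#' gated-positive events only (NA when there are none).
#'
#' @param events Data frame of events.
#' @param gate An `ev_gate` from [set_gate()].
#' @return A list with `percent_positive`, `mfi_all`, `mfi_positive`,
#'   `n_events`, `n_positive`.
#' @export
quantify_positive <- function(events, gate) {
  stopifnot(inherits(gate, "ev_gate"))
  x <- events[[flow_channel_column(gate$channel)]]
  if (is.null(x) || length(x) == 0L) {
    stop("empty event set", call. = FALSE)
  }
  pos <- x > gate$threshold_adu
  list(percent_positive = 100 * mean(pos),
       mfi_all = mean(x),
       mfi_positive = if (any(pos)) mean(x[pos]) else NA_real_,
       n_events = length(x),
       n_positive = sum(pos))
}

#' Dye-based sample purity
#'
#' Fraction of events above a red (membrane-dye) gate: with every vesicle
#' dye-labelled, this estimates the vesicular fraction of the particle
#' population.
#'
#' @param events Data frame of events.
#' @param red_gate An `ev_gate` on the red channel (set against an unstained
#'   control).
#' @return Percent of dye-positive events (0-100).
#' @export
purity <- function(events, red_gate) {
  stopifnot(inherits(red_gate, "ev_gate"))
  if (red_gate$channel != "red") {
    stop("purity requires a red-channel gate", call. = FALSE)
  }
  quantify_positive(events, red_gate)$percent_positive
}
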