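# Synthetic widefield fields: immobile fluorophores and vesicles rendered as
# diffraction-limited Gaussian spots on a noisy camera background.

# Pixel-center coordinates (um) along one axis.
pixel_centers_um <- function(n_px, pixel_size_um) {
  (seq_len(n_px) - 0.5) * pixel_size_um
}

# Uniform placement with rejection to enforce a minimum pairwise separation
# and a margin keeping every spot's footprint inside the field.
place_spots <- function(n, width_um, height_um, min_sep_um, margin_um) {
  if (2 * margin_um >= width_um || 2 * margin_um >= height_um) {
    stop("field overcrowded: margin exceeds field size", call. = FALSE)
  }
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * n + 1000L
  min_sep2 <- min_sep_um^2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("field overcrowded: cannot place requested spots at the minimum separation",
           call. = FALSE)
    }
    x <- runif(1, margin_um, width_um - margin_um)
    y <- runif(1, margin_um, height_um - margin_um)
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (min(d2) < min_sep2) next
    }
    placed <- placed + 1L
    xs[placed] <- x
    ys[placed] <- y
  }
  data.frame(x_um = xs, y_um = ys)
}

# Add Gaussian spots to a signal matrix (rows = y, cols = x), amplitudes in
# ADU at the PSF peak.  Separable kernel evaluated on a local window.
render_spots <- function(signal, x_um, y_um, amplitude, pixel_size_um,
                         psf_sigma_um) {
  h <- nrow(signal)
  w <- ncol(signal)
  half <- ceiling(5 * psf_sigma_um / pixel_size_um)
  cx <- pixel_centers_um(w, pixel_size_um)
  cy <- pixel_centers_um(h, pixel_size_um)
  for (i in seq_along(x_um)) {
    if (amplitude[i] <= 0) next
    jc <- round(x_um[i] / pixel_size_um + 0.5)
    ic <- round(y_um[i] / pixel_size_um + 0.5)
    js <- max(1L, jc - half):min(w, jc + half)
    is <- max(1L, ic - half):min(h, ic + half)
    gx <- exp(-((cx[js] - x_um[i])^2) / (2 * psf_sigma_um^2))
    gy <- exp(-((cy[is] - y_um[i])^2) / (2 * psf_sigma_um^2))
    signal[is, js] <- signal[is, js] + amplitude[i] * outer(gy, gx)
  }
  signal
}

# Camera model: Poisson shot noise on (background + signal), Gaussian read
# noise, constant baseline, clipped at zero.
camera_frame <- function(signal, config) {
  h <- nrow(signal)
  w <- ncol(signal)
  shot <- if (isTRUE(config$shot_noise)) {
    matrix(rpois(h * w, lambda = config$background_adu + signal), h, w)
  } else {
    config$background_adu + signal
  }
  out <- shot + config$baseline_adu
  if (config$read_noise_adu > 0) {
    out <- out + matrix(rnorm(h * w, 0, config$read_noise_adu), h, w)
  }
  out[out < 0] <- 0
  out
}

#' Bleach-trace record
#'
#' One spot's background-subtracted intensity time course.  Step counting and
#' single-molecule acceptance are filled in by [classify_bleach_trace()].
#'
#' @param spot_id Identifier linking the trace to a spot call.
#' @param intensity_per_frame Numeric vector of background-subtracted
#'   intensities, one per frame.
#' @return An object of class `bleach_trace` with fields `spot_id`,
#'   `intensity_per_frame`, `n_steps_detected` (NA until classified) and
#'   `accepted_single` (NA until classified).
#' @export
bleach_trace <- function(spot_id, intensity_per_frame) {
  structure(list(spot_id = spot_id,
                 intensity_per_frame = as.numeric(intensity_per_frame),
                 n_steps_detected = NA_integer_,
                 accepted_single = NA),
            class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("Bleach trace '%s': %d frames, steps: %s, accepted single: %s\n",
              as.character(x$spot_id), length(x$intensity_per_frame),
              ifelse(is.na(x$n_steps_detected), "unclassified",
                     x$n_steps_detected),
              ifelse(is.na(x$accepted_single), "unclassified",
                     x$accepted_single)))
  invisible(x)
}

#' Simulate a reference-fluorophore field with photobleaching
#'
#' Emulates the single-molecule calibration experiment: purified fluorophores
#' adsorbed sparsely on glass, imaged as a time series under constant
#' illumination so that each molecule bleaches in a single discrete step.  A
#' configurable contaminant fraction of spots carries 2-4 fluorophores
#' (aggregates), which downstream step counting must reject.
#'
#' Spots are placed uniformly with a minimum pairwise separation of
#' `4 * psf_sigma_um` so they never overlap.  Each fluorophore receives an
#' independent exponential bleach lifetime; a spot's noiseless amplitude at
#' frame time t is (surviving fluorophores) x `unit_peak_adu`.
#'
#' @param config A [sim_image_config()]; its `n_frames` sets the length of the
#'   bleaching time course and its `seed` makes the output reproducible.
#' @param n_molecules Number of reference spots to place (>= 1).
#' @param unit_peak_adu Noiseless PSF-peak amplitude of one fluorophore (ADU).
#' @param bleach_rate_per_s Exponential bleach rate per fluorophore (1/s).
#' @param multi_fraction Fraction of spots carrying 2-4 fluorophores, in
#'   `[0, 1)`.
#' @return A list with components `stack` (an `ev_image_stack`), `traces`
#'   (list of [bleach_trace()] objects, one per spot, sampled at the spot's
#'   nearest pixel and background-subtracted), and `truth` (a data frame with
#'   `spot_id`, `x_um`, `y_um`, `copy_number_true`, `unit_peak_adu_true`,
#'   `condition_label`).
#' @examples
#' cfg <- sim_image_config(width_px = 128, height_px = 128, n_frames = 16,
#'                         frame_interval_s = 0.5, seed = 1)
#' ref <- simulate_reference_field(cfg, n_molecules = 10, unit_peak_adu = 100,
#'                                 bleach_rate_per_s = 0.2)
#' table(ref$truth$copy_number_true)
#' @export
simulate_reference_field <- function(config, n_molecules,
                                     unit_peak_adu = 100,
                                     bleach_rate_per_s = 0.1,
                                     multi_fraction = 0) {
  stopifnot(inherits(config, "sim_image_config"))
  check_scalar(n_molecules, "n_molecules", lower = 1, integerish = TRUE)
  check_scalar(unit_peak_adu, "unit_peak_adu", lower = 0, strict_lower = TRUE)
  check_scalar(bleach_rate_per_s, "bleach_rate_per_s", lower = 0,
               strict_lower = TRUE)
  check_probability(multi_fraction, "multi_fraction")
  if (multi_fraction >= 1) stop("'multi_fraction' must be < 1", call. = FALSE)
  local_seed(config$seed)

  width_um <- config$width_px * config$pixel_size_um
  height_um <- config$height_px * config$pixel_size_um
  margin <- 4 * config$psf_sigma_um
  pos <- place_spots(n_molecules, width_um, height_um,
                     min_sep_um = 4 * config$psf_sigma_um, margin_um = margin)

  is_multi <- runif(n_molecules) < multi_fraction
  copies <- ifelse(is_multi, sample(2:4, n_molecules, replace = TRUE), 1L)

  # Independent exponential lifetime per fluorophore.
  lifetimes <- lapply(copies, function(k) rexp(k, rate = bleach_rate_per_s))
  times <- (seq_len(config$n_frames) - 1L) * config$frame_interval_s
  surviving <- vapply(lifetimes, function(lt) {
    vapply(times, function(t) sum(lt > t), numeric(1))
  }, numeric(config$n_frames))
  if (config$n_frames == 1L) surviving <- matrix(surviving, nrow = 1L)

  frames <- vector("list", config$n_frames)
  for (f in seq_len(config$n_frames)) {
    signal <- matrix(0, config$height_px, config$width_px)
    signal <- render_spots(signal, pos$x_um, pos$y_um,
                           surviving[f, ] * unit_peak_adu,
                           config$pixel_size_um, config$psf_sigma_um)
    frames[[f]] <- camera_frame(signal, config)
  }
  stack <- image_stack(frames, config$pixel_size_um, config$frame_interval_s)

  spot_id <- sprintf("ref_%04d", seq_len(n_molecules))
  jc <- pmin(pmax(round(pos$x_um / config$pixel_size_um + 0.5), 1L),
             config$width_px)
  ic <- pmin(pmax(round(pos$y_um / config$pixel_size_um + 0.5), 1L),
             config$height_px)
  offset <- config$baseline_adu + config$background_adu
  traces <- lapply(seq_len(n_molecules), function(i) {
    vals <- vapply(frames, function(fr) fr[ic[i], jc[i]], numeric(1)) - offset
    bleach_trace(spot_id[i], vals)
  })

  truth <- data.frame(spot_id = spot_id, x_um = pos$x_um, y_um = pos$y_um,
                      copy_number_true = as.integer(copies),
                      unit_peak_adu_true = unit_peak_adu,
                      condition_label = "reference",
                      stringsAsFactors = FALSE)
  list(stack = stack, traces = traces, truth = truth)
}

# Draw integer copy numbers from a named distribution specification.
draw_copy_numbers <- function(spec, n) {
  if (!is.list(spec) || is.null(spec$name)) {
    stop("copy_number_distribution must be a list with a 'name' element",
         call. = FALSE)
  }
  switch(spec$name,
    fixed = {
      check_scalar(spec$k, "k", lower = 0, integerish = TRUE)
      rep(as.integer(spec$k), n)
    },
    poisson = {
      check_scalar(spec$lambda, "lambda", lower = 0)
      rpois(n, spec$lambda)
    },
    lognormal = {
      p <- if (!is.null(spec$mean)) {
        lognormal_params(spec$mean, spec$cv)
      } else {
        list(meanlog = spec$meanlog, sdlog = spec$sdlog)
      }
      as.integer(round(rlnorm(n, p$meanlog, p$sdlog)))
    },
    given = {
      if (length(spec$copies) != n) {
        stop("'given' copy numbers must have length n_vesicles", call. = FALSE)
      }
      as.integer(spec$copies)
    },
    stop(sprintf("unknown copy-number distribution '%s'", spec$name),
         call. = FALSE)
  )
}

#' Simulate a vesicle field with per-vesicle cargo copy numbers
#'
#' Renders each vesicle as a single diffraction-limited Gaussian spot whose
#' noiseless peak amplitude is `copy_number_true * unit_peak_adu`: the
#' intensity readout is exactly linear in cargo copies, which is the modelling
#' assumption the downstream copy-number estimator relies on.  Vesicles with
#' zero copies emit nothing but stay in the truth table (GFP-negative
#' vesicles are invisible to fluorescence detection).
#'
#' @param config A [sim_image_config()].
#' @param n_vesicles Number of vesicles to place (>= 1).
#' @param copy_number_distribution A list: `list(name = "fixed", k = )`,
#'   `list(name = "poisson", lambda = )`, `list(name = "lognormal", mean = ,
#'   cv = )` (or `meanlog`/`sdlog`), or `list(name = "given", copies = )`.
#'   Lognormal draws are rounded to integers.
#' @param unit_peak_adu Noiseless PSF-peak amplitude of one cargo copy (ADU).
#' @param max_density_per_10um2 Nominal density limit used by downstream QC
#'   (recorded as an attribute; the generator itself does not enforce it, so
#'   overcrowded fields can be produced on purpose to exercise the QC).
#' @param condition_label Free-text label stored in the truth table.
#' @param positions Optional data frame with `x_um`, `y_um` (one row per
#'   vesicle) overriding random placement, e.g. to pin spots to exact pixel
#'   centers in worked examples.
#' @return A list with components `stack` (`ev_image_stack`) and `truth`
#'   (data frame as in [simulate_reference_field()]).  The attribute
#'   `requested_density_per_um2` on the result records n / field area.
#' @examples
#' cfg <- sim_image_config(width_px = 128, height_px = 128, n_frames = 4,
#'                         seed = 3)
#' ev <- simulate_ev_field(cfg, n_vesicles = 5,
#'                         copy_number_distribution = list(name = "fixed", k = 5))
#' ev$truth$copy_number_true
#' @export
simulate_ev_field <- function(config, n_vesicles, copy_number_distribution,
                              unit_peak_adu = 100,
                              max_density_per_10um2 = 1,
                              condition_label = "condition",
                              positions = NULL) {
  stopifnot(inherits(config, "sim_image_config"))
  check_scalar(n_vesicles, "n_vesicles", lower = 1, integerish = TRUE)
  check_scalar(unit_peak_adu, "unit_peak_adu", lower = 0, strict_lower = TRUE)
  local_seed(config$seed)

  copies <- draw_copy_numbers(copy_number_distribution, n_vesicles)
  width_um <- config$width_px * config$pixel_size_um
  height_um <- config$height_px * config$pixel_size_um
  if (is.null(positions)) {
    margin <- 4 * config$psf_sigma_um
    pos <- place_spots(n_vesicles, width_um, height_um,
                       min_sep_um = 4 * config$psf_sigma_um,
                       margin_um = margin)
  } else {
    stopifnot(nrow(positions) == n_vesicles,
              all(c("x_um", "y_um") %in% names(positions)))
    pos <- positions
  }

  signal <- matrix(0, config$height_px, config$width_px)
  signal <- render_spots(signal, pos$x_um, pos$y_um, copies * unit_peak_adu,
                         config$pixel_size_um, config$psf_sigma_um)
  frames <- lapply(seq_len(config$n_frames),
                   function(f) camera_frame(signal, config))
  stack <- image_stack(frames, config$pixel_size_um, config$frame_interval_s)

  truth <- data.frame(
    spot_id = sprintf("ev_%04d", seq_len(n_vesicles)),
    x_um = pos$x_um, y_um = pos$y_um,
    copy_number_true = copies,
    unit_peak_adu_true = unit_peak_adu,
    condition_label = condition_label,
    stringsAsFactors = FALSE)
  out <- list(stack = stack, truth = truth)
  attr(out, "requested_density_per_um2") <- n_vesicles / (width_um * height_um)
  attr(out, "max_density_per_10um2") <- max_density_per_10um2
  out
}

#' Simulate idealized photobleaching traces at a controlled step:noise ratio
#'
#' Generates background-subtracted stepwise traces directly (no camera),
#' so the step classifier can be characterized at an exact signal-to-noise
#' ratio.  Steps are placed at distinct frames separated by at least
#' `min_dwell_frames`, with the first level starting no earlier than frame
#' `min_dwell_frames + 1` and the final zero level lasting at least
#' `min_dwell_frames` frames: this emulates recorded traces in which each
#' bleaching event is temporally resolvable.
#'
#' @param n_traces Number of traces.
#' @param n_steps True number of bleaching steps per trace (>= 1).
#' @param step_adu Intensity drop per step (ADU).
#' @param noise_sd Gaussian noise standard deviation (ADU); step:noise ratio
#'   is `step_adu / noise_sd`.
#' @param n_frames Trace length in frames.
#' @param min_dwell_frames Minimum dwell (frames) of every level.
#' @param seed Integer seed.
#' @return A list with `traces` (list of [bleach_trace()]) and `truth`
#'   (data frame with `spot_id`, `n_steps_true`).
#' @examples
#' sim <- simulate_bleach_traces(5, n_steps = 1, step_adu = 100,
#'                               noise_sd = 10, seed = 1)
#' count_bleach_steps(sim$traces[[1]]$intensity_per_frame)
#' @export
simulate_bleach_traces <- function(n_traces, n_steps, step_adu = 100,
                                   noise_sd = 10, n_frames = 32,
                                   min_dwell_frames = 3, seed = 1L) {
  check_scalar(n_traces, "n_traces", lower = 1, integerish = TRUE)
  check_scalar(n_steps, "n_steps", lower = 1, integerish = TRUE)
  check_scalar(step_adu, "step_adu", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(min_dwell_frames, "min_dwell_frames", lower = 1,
               integerish = TRUE)
  if (n_frames < (n_steps + 1) * min_dwell_frames) {
    stop("trace too short for the requested number of resolvable steps",
         call. = FALSE)
  }
  local_seed(seed)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    # Change points: n_steps distinct frames with the dwell constraint,
    # drawn by spacing a uniform choice of gaps.
    slots <- n_frames - (n_steps + 1) * min_dwell_frames
    extras <- if (slots > 0) {
      sort(sample.int(slots + n_steps, n_steps)) - seq_len(n_steps)
    } else {
      rep(0L, n_steps)
    }
    cps <- min_dwell_frames * seq_len(n_steps) + extras  # last frame of level
    level <- numeric(n_frames)
    lev <- n_steps
    prev <- 0L
    for (s in seq_len(n_steps)) {
      level[(prev + 1L):cps[s]] <- lev * step_adu
      prev <- cps[s]
      lev <- lev - 1L
    }
    # remaining frames stay at zero
    traces[[i]] <- bleach_trace(sprintf("trc_%05d", i),
                                level + rnorm(n_frames, 0, noise_sd))
  }
  truth <- data.frame(spot_id = sprintf("trc_%05d", seq_len(n_traces)),
                      n_steps_true = as.integer(n_steps),
                      stringsAsFactors = FALSE)
  list(traces = traces, truth = truth)
}
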