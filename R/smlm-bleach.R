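# Photobleaching step counting and single-fluorophore intensity calibration.

# Exact least-squares piecewise-constant segmentation by dynamic programming.
# Returns, for each model size m = 1..max_segments, the optimal residual sum
# of squares and the fitted segment boundaries/levels for the selected model.
segment_trace <- function(x, max_segments) {
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - s^2 / (j - i + 1), 0)
  }
  M <- min(max_segments, n)
  D <- matrix(Inf, M, n)      # D[m, j]: best RSS, m segments over 1..j
  B <- matrix(0L, M, n)       # backpointer: last segment starts at B[m, j]
  for (j in seq_len(n)) {
    D[1, j] <- seg_cost(1, j)
    B[1, j] <- 1L
  }
  for (m in 2:M) {
    for (j in m:n) {
      best <- Inf
      bt <- m
      for (t in (m - 1):(j - 1)) {
        v <- D[m - 1, t] + seg_cost(t + 1, j)
        if (v < best) {
          best <- v
          bt <- t + 1L
        }
      }
      D[m, j] <- best
      B[m, j] <- bt
    }
  }
  list(rss = D[, n], backtrack = function(m) {
    starts <- integer(m)
    j <- n
    for (k in m:1) {
      starts[k] <- B[k, j]
      j <- starts[k] - 1L
    }
    ends <- c(starts[-1] - 1L, n)
    levels <- vapply(seq_len(m), function(k) {
      mean(x[starts[k]:ends[k]])
    }, numeric(1))
    list(starts = starts, ends = ends, levels = levels)
  })
}

# Robust noise scale from first differences (a step affects one difference,
# so the MAD is insensitive to the steps themselves).
trace_noise_sd <- function(x) {
  mad(diff(x)) / sqrt(2)
}

#' Count photobleaching steps in an intensity trace
#'
#' Fits piecewise-constant models with 1 to `max_steps + 1` segments by exact
#' least-squares segmentation (dynamic programming over all change-point
#' placements) and selects the number of segments with a Bayesian-type
#' information criterion: penalized cost = RSS + c x (number of segments) x
#' log(trace length) x (noise variance estimate).  The default penalty factor
#' c = 4 is deliberately conservative (each segment contributes two
#' parameters — level and boundary — and change-point criteria additionally
#' charge for boundary-location uncertainty): genuine bleaching steps at
#' usable signal-to-noise are far larger than the penalty, while spurious
#' splits of pure noise must stay rare.  Ties (e.g. noiseless traces, where the noise estimate is zero) resolve to
#' the fewest segments.  Only downward level changes are counted as bleaching
#' steps.
#'
#' @param trace A [bleach_trace()] or numeric vector of background-subtracted
#'   intensities (>= 8 frames).
#' @param max_steps Largest number of change points considered (default 5).
#' @param penalty_factor Multiplier c of the per-segment penalty (default 4).
#' @return Integer number of downward steps detected.
#' @examples
#' count_bleach_steps(c(100, 100, 100, 100, 0, 0, 0, 0))   # 1
#' count_bleach_steps(c(200, 200, 200, 100, 100, 0, 0, 0)) # 2
#' @export
count_bleach_steps <- function(trace, max_steps = 5, penalty_factor = 4) {
  fit_bleach_trace(trace, max_steps, penalty_factor)$n_steps
}

# Full segmentation result: steps, final level, noise estimate.
fit_bleach_trace <- function(trace, max_steps = 5, penalty_factor = 4) {
  x <- if (inherits(trace, "bleach_trace")) trace$intensity_per_frame
       else as.numeric(trace)
  if (length(x) < 8L) {
    stop("trace too short: need at least 8 frames", call. = FALSE)
  }
  check_scalar(max_steps, "max_steps", lower = 1, integerish = TRUE)
  seg <- segment_trace(x, max_segments = max_steps + 1L)
  n <- length(x)
  sigma2 <- trace_noise_sd(x)^2
  penalized <- seg$rss + penalty_factor * seq_along(seg$rss) * log(n) * sigma2
  best <- min(penalized)
  m <- which(penalized <= best + 1e-8 * (1 + abs(best)))[1]
  fit <- seg$backtrack(m)
  dl <- diff(fit$levels)
  list(n_steps = as.integer(sum(dl < 0)),
       levels = fit$levels,
       starts = fit$starts,
       final_level = fit$levels[m],
       noise_sd = sqrt(sigma2))
}

#' Classify a bleach trace as single-molecule or not
#'
#' Fills in `n_steps_detected` and `accepted_single` on a [bleach_trace()].
#' A trace is accepted as a single fluorophore when exactly one downward step
#' is detected *and* the trace ends at background: the final fitted level must
#' lie within 3x the noise estimate of zero, otherwise the object did not
#' bleach completely and is rejected as non-bleaching.
#'
#' @param trace A [bleach_trace()].
#' @param max_steps Passed to [count_bleach_steps()].
#' @return The trace with `n_steps_detected` and `accepted_single` set.
#' @export
classify_bleach_trace <- function(trace, max_steps = 5) {
  stopifnot(inherits(trace, "bleach_trace"))
  fit <- fit_bleach_trace(trace, max_steps)
  tol <- 3 * fit$noise_sd + 1e-8 * (1 + max(abs(trace$intensity_per_frame)))
  trace$n_steps_detected <- fit$n_steps
  trace$accepted_single <- (fit$n_steps == 1L) &&
    (abs(fit$final_level) <= tol)
  trace
}

#' Extract per-spot bleaching traces from an image stack
#'
#' Samples each spot's peak pixel across all frames and subtracts the scalar
#' background, yielding the time course used for step counting.
#'
#' @param stack An `ev_image_stack`.
#' @param spots Spot-call data frame from [detect_spots()] (needs `peak_row`,
#'   `peak_col`); traces are extracted for every row.
#' @param background_adu Scalar background (same scale as the frames).
#' @return A list of [bleach_trace()] objects, one per spot, named by
#'   `spot_id`.
#' @export
extract_traces <- function(stack, spots, background_adu) {
  stopifnot(inherits(stack, "ev_image_stack"))
  check_scalar(background_adu, "background_adu", lower = 0)
  traces <- lapply(seq_len(nrow(spots)), function(i) {
    vals <- vapply(stack$frames, function(fr) {
      fr[spots$peak_row[i], spots$peak_col[i]]
    }, numeric(1)) - background_adu
    bleach_trace(spots$spot_id[i], vals)
  })
  names(traces) <- spots$spot_id
  traces
}

#' Calibrate the single-fluorophore unit intensity
#'
#' Keeps only reference spots whose bleaching trace is accepted as a single
#' fluorophore (exactly one downward step, complete bleach), and estimates
#' the unit intensity as the mean of their background-subtracted peak
#' intensities.  Multi-fluorophore contaminants are thereby rejected before
#' averaging, which is what makes the estimate unbiased.
#'
#' @param reference_spots Spot-call data frame (typically `status ==
#'   "retained"` rows from the reference field).
#' @param traces List of traces, either already classified or raw
#'   [bleach_trace()] objects (classified here); matched to spots by
#'   `spot_id`.
#' @param min_accepted Minimum number of accepted single-step spots required
#'   (default 30).
#' @param max_steps Passed to the classifier.
#' @return An object of class `unit_calibration`: a list with
#'   `mean_unit_peak_adu`, `cv_unit`, `n_accepted`, `n_reference`.
#' @export
calibrate_unit_intensity <- function(reference_spots, traces,
                                     min_accepted = 30, max_steps = 5) {
  check_scalar(min_accepted, "min_accepted", lower = 1, integerish = TRUE)
  ids <- vapply(traces, function(t) as.character(t$spot_id), character(1))
  hit <- match(reference_spots$spot_id, ids)
  if (anyNA(hit)) {
    stop("every reference spot needs a matching trace", call. = FALSE)
  }
  accepted <- logical(nrow(reference_spots))
  for (i in seq_len(nrow(reference_spots))) {
    tr <- traces[[hit[i]]]
    if (is.na(tr$accepted_single)) {
      tr <- classify_bleach_trace(tr, max_steps)
    }
    accepted[i] <- isTRUE(tr$accepted_single)
  }
  peaks <- reference_spots$peak_intensity_adu[accepted]
  if (length(peaks) < min_accepted) {
    stop(sprintf(
      "calibration underpowered: %d accepted single-step spots, need %d",
      length(peaks), min_accepted), call. = FALSE)
  }
  m <- mean(peaks)
  structure(list(mean_unit_peak_adu = m,
                 cv_unit = if (length(peaks) > 1) sd(peaks) / m else 0,
                 n_accepted = length(peaks),
                 n_reference = nrow(reference_spots)),
            class = "unit_calibration")
}

#' @export
print.unit_calibration <- function(x, ...) {
  cat(sprintf(
    "Single-fluorophore calibration\n  unit peak intensity: %.2f ADU (CV %.3f)\n  accepted single-step spots: %d of %d reference spots\n",
    x$mean_unit_peak_adu, x$cv_unit, x$n_accepted, x$n_reference))
  invisible(x)
}
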