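# Synthetic antibody-capture chip readouts with exported ground truth.

CHIP_MARKERS <- c("CD63", "CD81", "CD9")

#' Simulate tetraspanin-capture chip readouts
#'
#' Emulates a capture chip with spots printed with anti-CD63, anti-CD81 and
#' anti-CD9 antibodies plus a matched-isotype IgG control spot.  Each vesicle
#' carries a subset of the three tetraspanins (per-marker Bernoulli
#' frequencies, optionally correlated through a Gaussian-copula latent
#' factor).  A tetraspanin spot captures every vesicle carrying its marker;
#' vesicles carrying at least one tetraspanin additionally stick to
#' non-matching spots at `nonspecific_rate`.  Bare particles (empty marker
#' set) adhere only to the IgG spot, which captures any particle at
#' `nonspecific_rate` and thereby reports the nonspecific-binding background.
#'
#' Captured events carry a CF647 intensity (labelling-antibody signal
#' proportional to the number of tetraspanins carried) and a CF555 intensity
#' (anti-GFP labelling proportional to GFP copies).  A vesicle's GFP-positive
#' probability is the mean of `gfp_positive_fraction_by_marker` over the
#' markers it carries (zero for bare particles).
#'
#' @param n_events Number of vesicles/particles incubated on the chip.
#' @param tetraspanin_frequencies Named probabilities for CD63, CD81, CD9.
#' @param co_occurrence Latent correlation of marker carriage in `[0, 1)`
#'   (0 = independent markers).
#' @param gfp_positive_fraction_by_marker Named per-marker GFP+ fractions.
#' @param nonspecific_rate Probability of nonspecific adhesion (in `[0, 1]`).
#' @param seed Integer seed.
#' @param mean_copies_positive Mean GFP copies on GFP+ vesicles.
#' @param cf647_per_marker_adu CF647 ADU per tetraspanin carried.
#' @param cf555_per_copy_adu CF555 ADU per GFP copy.
#' @param bg_mean_adu,bg_sd_adu Fluorescence background (Gaussian, clipped
#'   at 0).
#' @param mean_diameter_nm,diameter_cv Lognormal particle-size distribution
#'   reported per captured event.
#' @param bare_fraction Fraction of incubated particles that carry no
#'   tetraspanin at all (non-vesicular contaminants), applied on top of the
#'   per-marker frequencies.
#' @return A list with `readouts` (named list of data frames for CD63, CD81,
#'   CD9, IgG; columns `capture_antibody`, `event_id`, `cf647_adu`,
#'   `cf555_adu`, `diameter_nm`) and `truth` (data frame: `event_id`,
#'   `has_cd63`, `has_cd81`, `has_cd9`, `gfp_copies_true`).
#' @export
simulate_chip_capture <- function(n_events,
                                  tetraspanin_frequencies =
                                    c(CD63 = 0.6, CD81 = 0.5, CD9 = 0.4),
                                  co_occurrence = 0,
                                  gfp_positive_fraction_by_marker =
                                    c(CD63 = 0.4, CD81 = 0.4, CD9 = 0.4),
                                  nonspecific_rate = 0.02, seed = 1L,
                                  mean_copies_positive = 70,
                                  cf647_per_marker_adu = 300,
                                  cf555_per_copy_adu = 2,
                                  bg_mean_adu = 5, bg_sd_adu = 2,
                                  mean_diameter_nm = 100, diameter_cv = 0.25,
                                  bare_fraction = 0) {
  check_scalar(n_events, "n_events", lower = 1, integerish = TRUE)
  freqs <- tetraspanin_frequencies[CHIP_MARKERS]
  gfrac <- gfp_positive_fraction_by_marker[CHIP_MARKERS]
  if (anyNA(freqs) || any(freqs < 0) || any(freqs > 1)) {
    stop("tetraspanin_frequencies must name CD63, CD81, CD9 with values in [0, 1]",
         call. = FALSE)
  }
  if (anyNA(gfrac) || any(gfrac < 0) || any(gfrac > 1)) {
    stop("gfp_positive_fraction_by_marker must name CD63, CD81, CD9 with values in [0, 1]",
         call. = FALSE)
  }
  check_probability(nonspecific_rate, "nonspecific_rate")
  check_probability(bare_fraction, "bare_fraction")
  if (co_occurrence < 0 || co_occurrence >= 1) {
    stop("co_occurrence must be in [0, 1)", call. = FALSE)
  }
  local_seed(seed)

  # Gaussian-copula marker carriage: common latent factor + independent part.
  common <- rnorm(n_events)
  carry <- sapply(CHIP_MARKERS, function(m) {
    z <- sqrt(co_occurrence) * common +
      sqrt(1 - co_occurrence) * rnorm(n_events)
    z < qnorm(freqs[[m]])
  })
  if (bare_fraction > 0) {
    carry[runif(n_events) < bare_fraction, ] <- FALSE
  }

  n_markers <- rowSums(carry)
  p_gfp <- ifelse(n_markers > 0, (carry %*% gfrac) / pmax(n_markers, 1), 0)
  gfp_pos <- runif(n_events) < p_gfp
  copies <- integer(n_events)
  copies[gfp_pos] <- 1L + rpois(sum(gfp_pos), mean_copies_positive - 1)

  bg <- function(n) pmax(rnorm(n, bg_mean_adu, bg_sd_adu), 0)
  p <- lognormal_params(mean_diameter_nm, diameter_cv)
  diam <- rlnorm(n_events, p$meanlog, p$sdlog)
  id <- sprintf("chip_%06d", seq_len(n_events))

  make_readout <- function(ab, captured) {
    k <- sum(captured)
    data.frame(
      capture_antibody = rep(ab, k),
      event_id = id[captured],
      cf647_adu = n_markers[captured] * cf647_per_marker_adu + bg(k),
      cf555_adu = copies[captured] * cf555_per_copy_adu + bg(k),
      diameter_nm = diam[captured],
      stringsAsFactors = FALSE)
  }

  readouts <- list()
  for (m in CHIP_MARKERS) {
    specific <- carry[, m]
    sticky <- (n_markers > 0) & !specific &
      (runif(n_events) < nonspecific_rate)
    readouts[[m]] <- make_readout(m, specific | sticky)
  }
  readouts[["IgG"]] <- make_readout("IgG", runif(n_events) < nonspecific_rate)

  truth <- data.frame(event_id = id,
                      has_cd63 = carry[, "CD63"],
                      has_cd81 = carry[, "CD81"],
                      has_cd9 = carry[, "CD9"],
                      gfp_copies_true = copies,
                      stringsAsFactors = FALSE)
  list(readouts = readouts, truth = truth)
}
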