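# Synthetic nanoflow-cytometry event tables with exported ground truth.

#' Simulate nanoflow-cytometry events
#'
#' Generates per-particle event records with three channels: side scatter
#' (SSC, the size proxy and trigger channel), green fluorescence (GFP cargo)
#' and red fluorescence (membrane dye).  SSC follows a strictly increasing
#' power law of particle diameter, `ssc = ssc_coefficient *
#' (d/100)^ssc_exponent`, times lognormal instrument noise.  Green intensity
#' is `gfp_copies_true * per-copy brightness` plus detector background; red
#' intensity is high iff the particle is dye-labelled.
#'
#' Vesicles (a fraction `purity` of events) are dye-labelled and may carry
#' GFP; non-vesicle contaminants are never dye-labelled and never carry GFP.
#' `gfp_positive_fraction` is the probability that a *vesicle* is GFP
#' positive; GFP-positive vesicles carry `1 + Poisson(mean_copies_positive -
#' 1)` copies.
#'
#' With `bead_mode = "four_modal"` the events are the silica size-standard
#' cocktail (68/91/113/155 nm monodisperse populations in equal proportion);
#' with `bead_mode = "concentration"` they are the 250 nm concentration
#' standard.  Bead events carry background-only fluorescence.
#'
#' @param n_events Number of events.
#' @param gfp_positive_fraction Probability a vesicle is GFP+ (in `[0, 1]`).
#' @param mean_copies_positive Mean GFP copies on positive vesicles.
#' @param purity Fraction of events that are vesicles (in `[0, 1]`).
#' @param bead_mode `NULL` (EV sample), `"four_modal"`, or `"concentration"`.
#' @param seed Integer seed.
#' @param mean_diameter_nm,diameter_cv Lognormal vesicle-diameter
#'   distribution (defaults 74 nm, CV 0.25).
#' @param ssc_coefficient SSC in ADU at 100 nm diameter.
#' @param ssc_exponent Power-law exponent of SSC vs diameter (> 0).
#' @param ssc_noise_cv Lognormal SSC noise CV (default 0.05).
#' @param bead_size_cv Within-population diameter CV of bead standards.
#' @param per_copy_brightness_adu Green ADU per GFP copy.
#' @param bg_mean_adu,bg_sd_adu Fluorescence detector background (both
#'   channels), Gaussian clipped at zero.
#' @param red_label_mean_adu Mean red intensity of dye-labelled particles
#'   (lognormal, CV 0.3).
#' @return A list with `events` (data frame: `event_id`, `ssc_adu`,
#'   `fl_green_adu`, `fl_red_adu`) and `truth` (data frame: `event_id`,
#'   `diameter_nm_true`, `is_vesicle`, `is_dye_labelled`, `gfp_copies_true`).
#' @examples
#' beads <- simulate_flow_events(1000, bead_mode = "four_modal", seed = 1)
#' range(beads$truth$diameter_nm_true)
#' @export
simulate_flow_events <- function(n_events, gfp_positive_fraction = 0,
                                 mean_copies_positive = 70, purity = 1,
                                 bead_mode = NULL, seed = 1L,
                                 mean_diameter_nm = 74, diameter_cv = 0.25,
                                 ssc_coefficient = 1000, ssc_exponent = 4,
                                 ssc_noise_cv = 0.05, bead_size_cv = 0.02,
                                 per_copy_brightness_adu = 2,
                                 bg_mean_adu = 5, bg_sd_adu = 2,
                                 red_label_mean_adu = 500) {
  check_scalar(n_events, "n_events", lower = 1, integerish = TRUE)
  check_probability(gfp_positive_fraction, "gfp_positive_fraction")
  check_probability(purity, "purity")
  check_scalar(mean_copies_positive, "mean_copies_positive", lower = 1)
  check_scalar(ssc_exponent, "ssc_exponent", lower = 0, strict_lower = TRUE)
  local_seed(seed)

  bg <- function(n) pmax(rnorm(n, bg_mean_adu, bg_sd_adu), 0)

  if (!is.null(bead_mode)) {
    bead_mode <- match.arg(bead_mode, c("four_modal", "concentration"))
    base <- if (bead_mode == "four_modal") {
      sample(c(68, 91, 113, 155), n_events, replace = TRUE)
    } else {
      rep(250, n_events)
    }
    diam <- base * exp(rnorm(n_events, 0, sqrt(log1p(bead_size_cv^2))))
    is_vesicle <- rep(FALSE, n_events)
    is_dye <- rep(FALSE, n_events)
    copies <- rep(0L, n_events)
  } else {
    p <- lognormal_params(mean_diameter_nm, diameter_cv)
    diam <- rlnorm(n_events, p$meanlog, p$sdlog)
    is_vesicle <- runif(n_events) < purity
    is_dye <- is_vesicle  # membrane dye labels every vesicle
    copies <- integer(n_events)
    pos <- is_vesicle & (runif(n_events) < gfp_positive_fraction)
    copies[pos] <- 1L + rpois(sum(pos), mean_copies_positive - 1)
  }

  ssc <- ssc_coefficient * (diam / 100)^ssc_exponent *
    exp(rnorm(n_events, 0, sqrt(log1p(ssc_noise_cv^2))))
  green <- copies * per_copy_brightness_adu + bg(n_events)
  red <- bg(n_events)
  red[is_dye] <- rlnorm(sum(is_dye), log(red_label_mean_adu) -
                          log1p(0.3^2) / 2, sqrt(log1p(0.3^2)))

  id <- sprintf("evt_%06d", seq_len(n_events))
  list(
    events = data.frame(event_id = id, ssc_adu = ssc, fl_green_adu = green,
                        fl_red_adu = red, stringsAsFactors = FALSE),
    truth = data.frame(event_id = id, diameter_nm_true = diam,
                       is_vesicle = is_vesicle, is_dye_labelled = is_dye,
                       gfp_copies_true = copies, stringsAsFactors = FALSE)
  )
}
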