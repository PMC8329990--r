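# Synthetic-data generator: determinism, truth conservation, rendering
# linearity, and the statistical structure of the simulated populations.

test_that("reference field echoes parameters and conserves truth", {
  cfg <- sim_image_config(width_px = 160, height_px = 160, n_frames = 8,
                          frame_interval_s = 0.5, seed = 1)
  ref <- simulate_reference_field(cfg, n_molecules = 50, unit_peak_adu = 100,
                                  bleach_rate_per_s = 0.1, multi_fraction = 0)
  expect_equal(nrow(ref$truth), 50)
  expect_true(all(ref$truth$copy_number_true == 1))
  expect_equal(ref$truth$unit_peak_adu_true, rep(100, 50))
  expect_false(anyDuplicated(ref$truth$spot_id) > 0)
  expect_length(ref$traces, 50)
  # positions inside the field
  side <- 160 * cfg$pixel_size_um
  expect_true(all(ref$truth$x_um > 0 & ref$truth$x_um < side))
  expect_true(all(ref$truth$y_um > 0 & ref$truth$y_um < side))
  # minimum pairwise separation of 4 sigma
  d <- as.matrix(dist(ref$truth[, c("x_um", "y_um")]))
  diag(d) <- Inf
  expect_gte(min(d), 4 * cfg$psf_sigma_um - 1e-9)
})

test_that("identical config and seed give bit-identical stacks", {
  cfg <- sim_image_config(width_px = 64, height_px = 64, n_frames = 3,
                          seed = 1)
  a <- simulate_reference_field(cfg, n_molecules = 5)
  b <- simulate_reference_field(cfg, n_molecules = 5)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  ev1 <- simulate_ev_field(cfg, 5, list(name = "poisson", lambda = 10))
  ev2 <- simulate_ev_field(cfg, 5, list(name = "poisson", lambda = 10))
  expect_identical(ev1$stack$frames, ev2$stack$frames)
})

test_that("multi-fluorophore contamination is binomial across seeds", {
  # Binomial(100, 0.2) spot-level contamination: the mean count over many
  # seeds concentrates at 20 (se of the mean ~0.28 at 200 seeds).
  counts <- vapply(seq_len(200), function(s) {
    cfg <- sim_image_config(width_px = 256, height_px = 256, n_frames = 1,
                            seed = s)
    ref <- simulate_reference_field(cfg, n_molecules = 100,
                                    multi_fraction = 0.2)
    sum(ref$truth$copy_number_true >= 2)
  }, numeric(1))
  expect_gte(mean(counts), 19)
  expect_lte(mean(counts), 21)
})

test_that("overcrowded fields are refused", {
  cfg <- sim_image_config(width_px = 16, height_px = 16, n_frames = 1,
                          seed = 1)
  expect_error(simulate_reference_field(cfg, n_molecules = 200),
               "overcrowded")
})

test_that("vesicle rendering is exactly linear in copy number", {
  cfg <- noiseless_config(width_px = 128, n_frames = 1, background_adu = 40)
  pos <- grid_positions(3, cfg, spacing_px = 40)
  ev <- simulate_ev_field(cfg, 3, list(name = "given", copies = c(1, 2, 4)),
                          unit_peak_adu = 100, positions = pos)
  fr <- ev$stack$frames[[1]]
  px <- round(pos$x_um / cfg$pixel_size_um + 0.5)
  py <- round(pos$y_um / cfg$pixel_size_um + 0.5)
  peaks <- fr[cbind(py, px)] - 40
  expect_identical(peaks, c(100, 200, 400))
})

test_that("fixed copy-number rendering puts every spot at k x unit", {
  cfg <- noiseless_config(width_px = 256, n_frames = 1, background_adu = 40)
  pos <- grid_positions(10, cfg, spacing_px = 24)
  ev <- simulate_ev_field(cfg, 10, list(name = "fixed", k = 5),
                          unit_peak_adu = 100, positions = pos)
  fr <- ev$stack$frames[[1]]
  px <- round(pos$x_um / cfg$pixel_size_um + 0.5)
  py <- round(pos$y_um / cfg$pixel_size_um + 0.5)
  expect_true(all(fr[cbind(py, px)] - 40 == 500))
  expect_true(all(ev$truth$copy_number_true == 5))
})

test_that("zero-copy vesicles emit nothing but stay in truth", {
  cfg <- noiseless_config(width_px = 64, n_frames = 1, background_adu = 40)
  pos <- grid_positions(2, cfg, spacing_px = 30)
  ev <- simulate_ev_field(cfg, 2, list(name = "given", copies = c(0, 5)),
                          positions = pos)
  fr <- ev$stack$frames[[1]]
  px <- round(pos$x_um / cfg$pixel_size_um + 0.5)
  py <- round(pos$y_um / cfg$pixel_size_um + 0.5)
  expect_equal(fr[py[1], px[1]], 40)       # nothing rendered
  expect_gt(fr[py[2], px[2]], 40)
  expect_equal(nrow(ev$truth), 2)
})

test_that("lognormal copy numbers concentrate at the requested mean", {
  cfg <- sim_image_config(width_px = 950, height_px = 950, n_frames = 1,
                          seed = 3)
  ev <- simulate_ev_field(cfg, 500,
                          list(name = "lognormal", mean = 70, cv = 0.5))
  m <- mean(ev$truth$copy_number_true)
  expect_lt(abs(m - 70) / 70, 0.05)
})

test_that("unknown copy-number distribution is a config error", {
  cfg <- sim_image_config(width_px = 64, height_px = 64, seed = 1)
  expect_error(simulate_ev_field(cfg, 2, list(name = "cauchy")), "unknown")
})

test_that("rendered frames are non-negative even with heavy read noise", {
  cfg <- sim_image_config(width_px = 64, height_px = 64, n_frames = 2,
                          background_adu = 0, read_noise_adu = 50,
                          baseline_adu = 0, seed = 9)
  ref <- simulate_reference_field(cfg, n_molecules = 3)
  expect_true(all(vapply(ref$stack$frames, function(f) all(f >= 0),
                         logical(1))))
})

test_that("flow bead cocktail produces four SSC modes in diameter order", {
  beads <- simulate_flow_events(4000, bead_mode = "four_modal", seed = 1)
  truth <- beads$truth
  expect_true(all(!truth$is_vesicle) && all(!truth$is_dye_labelled))
  pop <- cut(truth$diameter_nm_true, c(0, 80, 102, 134, Inf),
             labels = c(68, 91, 113, 155))
  med <- tapply(beads$events$ssc_adu, pop, median)
  expect_true(all(diff(med) > 0))
})

test_that("null GFP condition is background-only in the green channel", {
  sim <- simulate_flow_events(2000, gfp_positive_fraction = 0, seed = 2)
  expect_true(all(sim$truth$gfp_copies_true == 0))
  expect_lt(max(sim$events$fl_green_adu), 30)  # background ~N(5, 2), clipped
})

test_that("flow purity structure follows the requested vesicle fraction", {
  sim <- simulate_flow_events(10000, purity = 0.85, seed = 5)
  frac <- mean(sim$truth$is_dye_labelled)
  expect_lt(abs(frac - 0.85), 0.01)
  # non-vesicle particles are never dye-labelled
  expect_true(all(!sim$truth$is_dye_labelled[!sim$truth$is_vesicle]))
})

test_that("chip capture respects the tetraspanin matching rule", {
  s0 <- simulate_chip_capture(500, nonspecific_rate = 0, seed = 3)
  for (m in c("CD63", "CD81", "CD9")) {
    col <- paste0("has_", tolower(sub("CD", "cd", m)))
    carried <- s0$truth[[col]][match(s0$readouts[[m]]$event_id,
                                     s0$truth$event_id)]
    expect_true(all(carried))
  }
  expect_equal(nrow(s0$readouts$IgG), 0)
})

test_that("single-marker chip populations appear on other spots only nonspecifically", {
  s9 <- simulate_chip_capture(
    500, tetraspanin_frequencies = c(CD63 = 0, CD81 = 0, CD9 = 1),
    nonspecific_rate = 0.05, seed = 4)
  expect_equal(nrow(s9$readouts$CD9), 500)
  expect_lt(nrow(s9$readouts$CD63), 500 * 0.05 * 3)
  expect_lt(nrow(s9$readouts$CD81), 500 * 0.05 * 3)
})

test_that("chip frequencies outside [0, 1] are a config error", {
  expect_error(simulate_chip_capture(
    100, tetraspanin_frequencies = c(CD63 = 1.2, CD81 = 0.5, CD9 = 0.4)),
    "\\[0, 1\\]")
})

test_that("bleach-trace generator hits the requested step count and SNR", {
  sim <- simulate_bleach_traces(50, n_steps = 3, step_adu = 100,
                                noise_sd = 0, n_frames = 32, seed = 6)
  for (tr in sim$traces[1:5]) {
    lev <- unique(tr$intensity_per_frame)
    expect_setequal(lev, c(300, 200, 100, 0))
  }
  expect_true(all(sim$truth$n_steps_true == 3))
})
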