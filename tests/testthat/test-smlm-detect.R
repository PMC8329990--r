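# Thresholded spot detection against a brute-force oracle, area filtering
# and density QC.

test_that("a bright noiseless spot is detected with sub-pixel centroid accuracy", {
  cfg <- noiseless_config(width_px = 64, n_frames = 1, background_adu = 100)
  pos <- data.frame(x_um = 31.7 * cfg$pixel_size_um,
                    y_um = 30.2 * cfg$pixel_size_um)
  ev <- simulate_ev_field(cfg, 1, list(name = "fixed", k = 4),
                          unit_peak_adu = 100, positions = pos)  # peak 5x bg
  img <- average_frames(ev$stack, 1)
  spots <- detect_spots(img, 100)
  expect_equal(nrow(spots), 1)
  expect_lt(abs(spots$centroid_x_um - pos$x_um), 0.5 * cfg$pixel_size_um)
  expect_lt(abs(spots$centroid_y_um - pos$y_um), 0.5 * cfg$pixel_size_um)
})

test_that("a peak at exactly 2x background is not detected (strict rule)", {
  cfg <- noiseless_config(width_px = 64, n_frames = 1, background_adu = 100)
  pos <- grid_positions(1, cfg, spacing_px = 32)
  ev <- simulate_ev_field(cfg, 1, list(name = "fixed", k = 1),
                          unit_peak_adu = 100, positions = pos)  # peak = 200
  img <- average_frames(ev$stack, 1)
  expect_equal(max(img$data), 200)
  expect_equal(nrow(detect_spots(img, 100)), 0)
  # nudging the peak strictly above 2x background detects it
  ev2 <- simulate_ev_field(cfg, 1, list(name = "fixed", k = 1),
                           unit_peak_adu = 101, positions = pos)
  expect_equal(nrow(detect_spots(average_frames(ev2$stack, 1), 100)), 1)
})

test_that("a blank image yields no spot calls", {
  img <- ev_image(matrix(50, 32, 32), 0.108)
  expect_equal(nrow(detect_spots(img, 50)), 0)
})

test_that("invalid background is rejected", {
  img <- ev_image(matrix(50, 8, 8), 0.108)
  expect_error(detect_spots(img, 0), "invalid background")
})

test_that("detection matches the brute-force flood-fill oracle", {
  set.seed(33)
  for (rep in 1:20) {
    conn <- if (rep %% 2 == 0) 8 else 4
    img <- ev_image(matrix(runif(64^2, 0, 300), 64, 64), 0.1)
    bg <- 100
    spots <- detect_spots(img, bg, connectivity = conn, keep_pixels = TRUE)
    got <- lapply(attr(spots, "pixels"), sort)
    got <- got[order(vapply(got, min, numeric(1)))]
    want <- flood_fill_components(img$data > 2 * bg, connectivity = conn)
    expect_equal(length(got), length(want))
    expect_equal(unname(got), lapply(want, as.integer))
    # per-spot summaries agree with loop-based recomputation
    ord <- order(vapply(attr(spots, "pixels"), min, numeric(1)))
    oracle <- lapply(want, oracle_spot_summary, img = img$data,
                     background = bg, pixel_size_um = 0.1)
    pull <- function(f) vapply(oracle, `[[`, numeric(1), f)
    expect_equal(spots$area_um2[ord], pull("area_um2"))
    expect_equal(spots$centroid_x_um[ord], pull("centroid_x_um"))
    expect_equal(spots$centroid_y_um[ord], pull("centroid_y_um"))
    expect_equal(spots$peak_intensity_adu[ord], pull("peak"))
    expect_equal(spots$integrated_intensity_adu[ord], pull("integrated"))
  }
})

test_that("area filter annotates statuses over the closed retained interval", {
  spots <- data.frame(spot_id = c("a", "b", "c", "d", "e"),
                      area_um2 = c(0.05, 0.5, 12, 0.1, 10),
                      status = "retained", stringsAsFactors = FALSE)
  out <- filter_spots(spots)
  expect_equal(out$status,
               c("removed_small", "retained", "removed_large",
                 "retained", "retained"))  # boundaries inclusive
  expect_equal(sum(out$status == "retained") +
                 sum(out$status == "removed_small") +
                 sum(out$status == "removed_large"), nrow(spots))
})

test_that("status conservation holds on simulated fields", {
  cfg <- sim_image_config(width_px = 300, height_px = 300, n_frames = 4,
                          seed = 14)
  ev <- simulate_ev_field(cfg, 40, list(name = "lognormal", mean = 50,
                                        cv = 0.5))
  img <- average_frames(ev$stack, 4)
  bg <- estimate_background(img)
  spots <- filter_spots(detect_spots(img, bg))
  expect_equal(sum(table(spots$status)), nrow(spots))
  expect_true(all(spots$status %in%
                    c("retained", "removed_small", "removed_large")))
  # retained spots satisfy integrated >= peak >= 0
  ret <- spots[spots$status == "retained", ]
  expect_true(all(ret$integrated_intensity_adu >= ret$peak_intensity_adu))
  expect_true(all(ret$peak_intensity_adu >= 0))
})

test_that("density QC passes below and fails above 1 spot per 10 um^2", {
  mk <- function(n) data.frame(status = rep("retained", n))
  q1 <- qc_density(mk(400), 65^2)
  expect_true(q1$pass)                      # 400/4225 = 0.0947 < 0.1
  expect_equal(q1$density_per_um2, 400 / 4225)
  expect_false(qc_density(mk(500), 65^2)$pass)
  q0 <- qc_density(mk(0), 65^2)
  expect_true(q0$pass)
  expect_equal(q0$density_per_um2, 0)
})
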