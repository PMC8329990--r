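# Nanoflow cytometry: size curve, concentration, gating, percent-positive,
# purity.

test_that("fitted size curve anchors knots at bead modes", {
  beads <- simulate_flow_events(4000, bead_mode = "four_modal", seed = 7)
  curve <- fit_size_curve(beads$events)
  expect_equal(curve$knots$diameter_nm, c(68, 91, 113, 155))
  # knot identity: exact, including the lowest mode -> 68 nm
  expect_identical(predict(curve, curve$knots$ssc_adu),
                   curve$knots$diameter_nm)
  expect_equal(predict(curve, curve$knots$ssc_adu[1]), 68)
})

test_that("two-knot curve matches the closed-form log-log interpolation", {
  sc <- size_curve(c(1000, 2000), c(100, 200))
  expect_equal(predict(sc, 1500), 150)
  # closed form: d = exp(log d1 + slope * (log s - log s1))
  s <- c(1100, 1700, 1900)
  slope <- log(2) / log(2)
  expect_equal(predict(sc, s), exp(log(100) + slope * log(s / 1000)))
})

test_that("fitted curve is non-decreasing over its domain", {
  beads <- simulate_flow_events(4000, bead_mode = "four_modal", seed = 8)
  curve <- fit_size_curve(beads$events)
  g <- exp(seq(log(min(curve$knots$ssc_adu)), log(max(curve$knots$ssc_adu)),
               length.out = 400))
  expect_true(all(diff(predict(curve, g)) >= -1e-12))
})

test_that("degenerate bead data is refused", {
  ev <- data.frame(ssc_adu = rep(1000, 100))
  expect_error(fit_size_curve(ev, c(68, 91)), "degenerate bead data")
})

test_that("diameters recover the generative mean through the SSC model", {
  beads <- simulate_flow_events(4000, bead_mode = "four_modal", seed = 7)
  curve <- fit_size_curve(beads$events)
  sim <- simulate_flow_events(5000, seed = 9)  # 74 nm mean, 5% SSC noise
  out <- apply_size_curve(sim$events, curve)
  expect_lt(abs(out$summary$mean_nm - 74), 1)
})

test_that("size assignment flags out-of-range events when not extrapolating", {
  sc <- size_curve(c(1000, 2000), c(100, 200))
  ev <- data.frame(event_id = c("a", "b", "c"),
                   ssc_adu = c(500, 1500, 3000))
  out <- apply_size_curve(ev, sc, extrapolate = FALSE)
  expect_equal(out$diameters$below_range, c(TRUE, FALSE, FALSE))
  expect_equal(out$diameters$above_range, c(FALSE, FALSE, TRUE))
  expect_true(is.na(out$diameters$diameter_nm[1]))
  expect_equal(out$diameters$diameter_nm[2], 150)

  empty <- apply_size_curve(data.frame(ssc_adu = numeric(0)), sc)
  expect_false(empty$summary$defined)
})

test_that("concentration scales proportionally from the bead standard", {
  cal <- calibrate_concentration(1000, 1e10)
  expect_equal(estimate_concentration(cal, 2000, 100), 2e12)
  expect_equal(estimate_concentration(cal, 0), 0)
  # doubling the sample rate exactly doubles the estimate
  expect_equal(estimate_concentration(cal, 4000, 100),
               2 * estimate_concentration(cal, 2000, 100))
  expect_error(calibrate_concentration(0, 1e10), "invalid standard")
})

test_that("Poisson counting noise keeps concentration error small", {
  set.seed(71)
  true_conc <- 5e11
  rel_err <- replicate(100, {
    bead_counts <- rpois(1, 3000)
    sample_counts <- rpois(1, 3000)
    cal <- calibrate_concentration(bead_counts, 1e10)
    est <- estimate_concentration(cal, sample_counts, 50)
    abs(est - true_conc) / true_conc
  })
  expect_lt(mean(rel_err), 0.05)  # ~sqrt(2/3000) expected
})

test_that("blank subtraction clips at zero and checks binning", {
  expect_equal(subtract_blank(100, 10), 90)
  expect_equal(subtract_blank(5, 10), 0)
  expect_equal(subtract_blank(c(3, 4), c(0, 0)), c(3, 4))
  expect_error(subtract_blank(1:3, 1:2), "binning mismatch")
})

test_that("gate threshold is the control quantile", {
  zeros <- data.frame(fl_green_adu = rep(0, 500))
  expect_equal(set_gate(zeros, "green")$threshold_adu, 0)

  set.seed(81)
  ctrl <- data.frame(fl_green_adu = runif(2000, 0, 100))
  g <- set_gate(ctrl, "green", quantile = 0.995)
  expect_lt(abs(g$threshold_adu - 99.5), 0.5)
  # control self-gating stays near the nominal false-positive rate
  self_pct <- quantify_positive(ctrl, g)$percent_positive
  se3 <- 3 * sqrt(0.005 * 0.995 / 2000) * 100
  expect_lte(self_pct, 0.5 + se3)

  expect_error(set_gate(data.frame(fl_green_adu = rep(0, 50)), "green"),
               "control underpowered")
})

test_that("percent positive uses the strictly-above rule", {
  ev <- data.frame(fl_green_adu = c(0, 0, 10, 10))
  g <- structure(list(channel = "green", threshold_adu = 5, quantile = NA,
                      control_id = NULL, n_control = NA), class = "ev_gate")
  q <- quantify_positive(ev, g)
  expect_equal(q$percent_positive, 50)
  expect_equal(q$mfi_all, 5)
  expect_equal(q$mfi_positive, 10)
  # events exactly at the threshold are negative
  g$threshold_adu <- 10
  expect_equal(quantify_positive(ev, g)$percent_positive, 0)
  expect_error(quantify_positive(ev[0, , drop = FALSE], g), "empty")
})

test_that("simulated GFP+ fraction is recovered through the gate", {
  ctrl <- simulate_flow_events(5000, gfp_positive_fraction = 0, seed = 22)
  gate <- set_gate(ctrl$events, "green")
  sim <- simulate_flow_events(5000, gfp_positive_fraction = 0.4,
                              mean_copies_positive = 70, seed = 21)
  q <- quantify_positive(sim$events, gate)
  expect_lt(abs(q$percent_positive - 40), 2)
})

test_that("purity reports the dye-positive fraction", {
  ev <- data.frame(fl_red_adu = rep(c(100, 0), c(850, 150)))
  rg <- structure(list(channel = "red", threshold_adu = 50, quantile = NA,
                       control_id = NULL, n_control = NA), class = "ev_gate")
  expect_equal(purity(ev, rg), 85)
  expect_equal(purity(data.frame(fl_red_adu = rep(0, 10)), rg), 0)

  unstained <- simulate_flow_events(1000, purity = 0, seed = 24)
  gate <- set_gate(unstained$events, "red")
  mix <- simulate_flow_events(10000, purity = 0.85, seed = 23)
  expect_lt(abs(purity(mix$events, gate) - 85), 1)
})
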