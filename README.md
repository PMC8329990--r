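# evcargo

Single-vesicle quantification of protein cargo in engineered extracellular
vesicles (EVs).

## The problem

Cells engineered to overexpress an EV-sorting protein (CD63, CD81, CD9,
TSPAN14, CD47, SDCBP, APMAP, ...) fused to a cargo protein (GFP as the model
cargo) secrete vesicles whose loading is highly heterogeneous: only part of
the vesicle population carries cargo at all, and loaded vesicles carry
anywhere from a few to hundreds of molecules. Bulk readouts (Western blots)
cannot see this heterogeneity. evcargo implements the quantitative analysis
for three single-vesicle readouts, the statistics that compare engineering
conditions across them, and a synthetic-data generator with exported ground
truth so that every stage is verifiable by parameter recovery:

- **Single-molecule copy counting from widefield image stacks.** Vesicles
  appear as diffraction-limited spots; with the single-fluorophore unit
  intensity *u* calibrated from reference fluorophore fields (accepting only
  spots whose photobleaching trace shows exactly one downward step), the
  copy number of a vesicle spot with background-subtracted peak intensity
  *I* is simply *n = I / u*, with a detection limit of 3 molecules.
  Pipeline: 4-frame averaging → 65 µm center crop → robust background →
  threshold strictly above 2× background → connected components →
  area filter [0.1, 10] µm² → density QC (< 1 spot / 10 µm²).
- **Nanoflow cytometry.** Side-scatter (SSC) to diameter via a monotone
  log–log standard curve anchored at the 68/91/113/155 nm silica bead
  modes; concentration from a 250 nm counting standard; fluorescence gates
  at the 99.5th percentile of a negative control; %positive, MFI (total
  population and positives), and membrane-dye purity.
- **Tetraspanin-capture chips.** Per capture spot (anti-CD63/CD81/CD9 +
  IgG isotype): %GFP⁺ = 100 × (CF555⁺ events) / (CF647⁺ events), CF555
  MFI, a 50–200 nm sizing window, and isotype-based background counts.
- **Statistics.** Kruskal–Wallis with Dunn's Bonferroni-adjusted post-hoc
  z tests; per-condition normalization to the untransfected control;
  Pearson r / R² between methods.

## Worked example

```r
library(evcargo)

# 1. Calibrate the unit intensity on a simulated reference-fluorophore field
cfg <- sim_image_config(width_px = 700, height_px = 700, n_frames = 24,
                        frame_interval_s = 0.5, seed = 42)
ref <- simulate_reference_field(cfg, n_molecules = 200, unit_peak_adu = 100,
                                bleach_rate_per_s = 0.3, multi_fraction = 0.1)
img   <- average_frames(ref$stack, 4)
bg    <- estimate_background(img)
spots <- filter_spots(detect_spots(img, bg))
spots <- spots[spots$status == "retained", ]
cal   <- calibrate_unit_intensity(spots, extract_traces(ref$stack, spots, bg))
cal
#> Single-fluorophore calibration
#>   unit peak intensity: 96.27 ADU (CV 0.068)
#>   accepted single-step spots: 95 of 143 reference spots

# 2. Quantify copy numbers on a simulated vesicle field (true mean 70, CV 0.5)
cfg2 <- sim_image_config(width_px = 950, height_px = 950, seed = 1070)
ev   <- simulate_ev_field(cfg2, 500, list(name = "lognormal", mean = 70, cv = 0.5))
res  <- quantify_stack(ev$stack, cal, crop_side_um = NULL)
summarize_condition(res$records, "TSPAN14-like")
#> Condition 'TSPAN14-like': 470 spots, 470 above detection, mean 69.2 copies/vesicle
```

The calibration accepts only reference spots whose trace bleached in a
single step (multi-fluorophore aggregates are rejected, which is what keeps
the mean unbiased at ~100 ADU), and the condition mean over above-detection
vesicles recovers the generative truth (the realized truth mean over
vesicles with ≥ 3 copies is 68.2 here) to within a few percent.

```r
# 3. Flow: size + gating
beads <- simulate_flow_events(4000, bead_mode = "four_modal", seed = 7)
curve <- fit_size_curve(beads$events)
predict(curve, curve$knots$ssc_adu[1])
#> [1] 68
ctrl <- simulate_flow_events(5000, gfp_positive_fraction = 0, seed = 22)
sim  <- simulate_flow_events(5000, gfp_positive_fraction = 0.4, seed = 21)
quantify_positive(sim$events, set_gate(ctrl$events, "green"))$percent_positive
#> [1] 39.02
apply_size_curve(sim$events, curve)$summary$mean_nm
#> [1] 74.12
```

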