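# chromamotion

Analysis tools for chromatic motion-vision experiments in *Drosophila*, in
which UV and green light are traded off against each other to locate the
**isoluminance point** — the UV intensity (on a 4-bit 0–15 scale, at fixed
calibrated green) at which a motion-driven response crosses zero — separately
for the ON-motion (brightening-edge, T4) and OFF-motion (darkening-edge, T5)
pathways. The ON pathway is substantially more UV-sensitive than the OFF
pathway, which creates a band of UV backgrounds on which a green object is
invisible to motion vision while the same trade-off makes UV objects on green
visible everywhere.

The package implements, as tested reusable components:

- **Stimulus generation** (`render_disc`, `render_competing_edges`,
  `build_green_mask`): looming discs with constant-velocity expansion
  parameterized by r/v (half-angle `atan((r/v) / t)`, 6.8° one second
  before collision at r/v = 120 ms), competing UV/green edge stimuli
  (eight 30° windows, 120 °/s, 4 Hz), and the green-channel luminance mask
  that matches green to UV irradiance site by site up to a constant factor
  (2.3 by default).
- **Behavioral analysis** (`fold_trials`, `disc_metric`, `edge_metric`,
  `estimate_isoluminance`, `population_curve`): ΔWBA (wingbeat amplitude
  difference) recordings are folded across mirror rotations, reduced to
  response-vs-UV tuning curves (100 ms post-expansion window for discs, 2 s
  stimulus mean for edges), and the isoluminance is the first upward zero
  crossing scanning from UV = 0, linearly interpolated, with cap-and-flag
  handling for restricted-range protocols.
- **Calcium-imaging pipeline** (`align_movie`, `detect_rois`, `roi_dff`,
  `roi_metric_curve`, `roi_isoluminance`, `analyze_movie`,
  `aggregate_isoluminance`): binary-template rigid alignment with a
  >25 px rejection rule, Gaussian-smoothing (FWHM 11 px) + flood-fill ROI
  segmentation at neural-column separations, ΔF/F₀ against a 1.5 s
  pre-stimulus baseline, a two-frame post-expansion response metric,
  responsiveness thresholds, and polarity-specific zero-crossing scans
  (downward from UV = 15 for ON cells, upward from UV = 0 for OFF cells,
  minimum-response fallback when no crossing exists), aggregated
  ROI → fly → population with equal fly weighting.
- **Hexagonal-lattice motion model** (`hex_sample`, `directional_contrasts`,
  `radial_motion`, `compare_modes`): images resampled on a compound-eye-like
  lattice of 120 × 104 px flat-topped hexagons (exactly 9360 pixels each),
  directional Weber contrast `C = (I_h − I_b) / I_b` from home/background
  facet groups, and radial ON/OFF vector sums with channel-asymmetric
  spectral weights for approach-vs-recede comparisons.
- **Synthetic data with known ground truth** (`ground_truth`,
  `simulate_behavior`, `simulate_movie`, `make_test_image`,
  `predict_visibility`) and the supporting statistics (`fdr_adjust`,
  `run_test`).

## Worked example

Simulate one fly on the compact competing-edge protocol (UV 3–9, ON and OFF
measured in the same fly) and estimate its isoluminance points:

```r
library(chromamotion)

gt  <- ground_truth(i_on = 4.5, i_off = 9.2, amplitude = 1,
                    noise_sd = 0.05, n_trials = 5, seed = 1)
rec <- simulate_behavior(gt, "edges_compact")
fly_isoluminance(rec)
#>   fly_id  protocol    value capped crossing_found
#> 1   fly1  edges_on 4.454168  FALSE           TRUE
#> 2   fly1 edges_off 9.000000   TRUE          FALSE
```

The ON estimate recovers the planted 4.5 to within the trial noise; the OFF
truth (9.2) lies above the compact protocol's range, so the estimate is
capped at UV = 9 and flagged — exactly how restricted-range estimates are
reported.

The full imaging pipeline on a synthetic movie with three ON-type ROIs whose
tuning crosses zero at UV = 5, with 2 px rigid jitter and pixel noise:

```r
rois <- data.frame(x = c(30, 72, 94), y = c(34, 92, 40),
                   polarity = "ON", isoluminance = 5)
mv  <- simulate_movie(rois, uv_levels = c(0, 2, 4, 5, 6, 7, 8, 9, 10, 12, 15),
                      n_reps = 2, image_size = 128, jitter_sd = 2,
                      noise_sd = 0.02, column_spacing = 24, seed = 1)
res <- analyze_movie(mv, "ON", min_separation = 24)
res$rois[, c("roi", "isoluminance", "crossing_found", "ref_response")]
#>   roi isoluminance crossing_found ref_response
#> 1   1     4.999171           TRUE    0.2671576
#> 2   2     4.990708           TRUE    0.2671090
#> 3   3     5.005461           TRUE    0.2667982
aggregate_isoluminance(res$rois)$grand_mean
#> [1] 4.99811
```

Alignment, segmentation and the zero-crossing scan recover the planted
isoluminance to well under 0.1 UV levels per ROI.

## Documentation

The methods vignette (`vignettes/chromamotion-methods.Rmd`) describes the
models, estimators, numerical choices and the scope of the synthetic
validation in detail.
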