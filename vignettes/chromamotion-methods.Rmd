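---
title: "Methods: chromatic ON/OFF motion analysis and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatic ON/OFF motion analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

Fly motion vision is split into an ON pathway (T4 cells, brightening edges)
and an OFF pathway (T5 cells, darkening edges). When a display trades UV
intensity (quantized 0–15) against a fixed, spatially calibrated green, each
pathway has an *isoluminance point*: the UV level at which its
motion-driven response crosses zero. The ON pathway is more UV-sensitive,
so its isoluminance $I_{ON}$ sits below the OFF pathway's $I_{OFF}$. Two
consequences organize everything in this package: a UV object on green has
motion contrast for at least one pathway at every UV level (the ON and OFF
visibility bands overlap), and a green object on a UV background between
$I_{ON}$ and $I_{OFF}$ generates no motion contrast for either pathway —
it is invisible to motion vision (`predict_visibility()`).

`chromamotion` implements the analysis chain that measures these
quantities behaviorally and neuronally, a hexagonal-lattice image model of
their ecological consequence, and synthetic generators that make every
stage testable against known ground truth.

# Stimulus geometry

**Looming discs.** An object of radius $r$ approaching at constant speed
$v$ subtends a half-angle $\theta(t) = \arctan\!\big(\tfrac{r/v}{t}\big)$
with $t$ the time remaining to collision; $r/v$ (120 ms in the standard
protocols) fully parameterizes the profile. Frames are sampled at
$t_k = k/\mathrm{rate}$ so the last expansion frame sits exactly at full
expansion ($\theta = 90^\circ$); the expanded disc is then held. Disc
membership on the azimuth–elevation grid uses great-circle angular
distance, because the stimulus is specified by angular size rather than by
screen projection. The grid (default 1°/bin, −20°…100° azimuth,
−50°…50° elevation — the imaging display span) must contain at least one
bin inside the starting disc (6.8° by default, the size one second before
collision), otherwise rendering refuses with a "too coarse" error. The
behavioral protocols never state a starting size; the imaging value is
assumed for both.

**Competing edges.** The display is divided into eight perspective-
corrected 30° windows. Per cycle (0.25 s), a green edge sweeps rightward
and a UV edge leftward across every window at
$30^\circ / 0.25\,\mathrm{s} = 120^\circ/\mathrm{s}$, repeating at 4 Hz for
2 s. The OFF stimulus is *constructed* as the ON frames in reverse
temporal order within each cycle, and counterclockwise stimuli as the
mirror image in azimuth — both identities are asserted bit-exactly in the
tests, which pins the implementation to the construction rather than to a
re-derivation. Edges are rendered hard (aliased); the projector's
antialiasing behavior is unknown and immaterial for the analyses here.

**Calibration.** UV and green scatter differently through the projection
screen, so the green channel carries a per-site luminance mask. Under a
linear display model (irradiance proportional to intensity — the measured
behavior of the display), `build_green_mask()` sets the mask to
`scale × UV irradiance` per site and reports the achieved ratio grid for
QC; the standard scale is 2.3, chosen so that isoluminance falls
mid-range. The doubled-green manipulation is exposed as a scalar mask
multiplier rather than a second calibration.

# Behavioral estimation

Tethered-flight turning is measured as ΔWBA (left-minus-right wingbeat
amplitude) at 500 Hz. Mirror-symmetric trials (counterclockwise rotations,
left-side discs) are sign-inverted and pooled (`fold_trials()`), which
doubles the per-stimulus trial count and cancels lateral bias. Metrics:
the mean over the half-open 100 ms window starting at full expansion for
discs (50 samples), and the mean over the 2 s stimulus for competing
edges. The window start is inclusive at the expansion-end sample.

`estimate_isoluminance()` scans the per-level mean response upward from
UV = 0 and returns the linear interpolation of the first pair with
$m_i \le 0 < m_{i+1}$. The strictness is deliberately asymmetric: a mean of
exactly zero on the lower side is a permitted crossing, matching a
"response greater than zero" criterion on the upper side. Multiple
crossings resolve to the first, since the scan direction is part of the
definition. Degenerate curves are capped and flagged rather than dropped:
an all-positive curve returns the lowest level, a curve with no crossing
returns the highest, both with `capped = TRUE`, and restricted-range
(compact, UV 3–9) estimates clamp to the range bounds. Whether real
all-positive full-range curves should instead be excluded is not
determined by the measurement; cap-and-flag keeps every fly visible to
downstream statistics, which can filter on the flags.

# Imaging pipeline

**Alignment.** A binary template is the Otsu-binarized mean image over the
trials of one designated stimulus — UV = 15 for ON cells and UV = 0 for
OFF cells, the levels driving the strongest responses. Each frame is
Otsu-binarized and its integer shift taken as the argmax of the spatial
cross-correlation with the template (FFT-based, searched within ±32 px);
recordings with any component exceeding 25 px are rejected outright.
Otsu is our choice: binarization is specified only as "binary", and a
global adaptive threshold is the least-surprising default. Alignment is
integer-pixel only, which makes it exactly idempotent and lets synthetic
tests demand exact recovery of planted integer jitter.

**ROI detection.** The mean stimulus image is smoothed with a Gaussian of
FWHM 11 px ($\sigma = \mathrm{FWHM} / 2\sqrt{2\ln 2}$). Strict local
maxima above a floor (mean + 1 SD of the smoothed image; no floor is
specified by the measurement itself) seed ROIs; seeds closer than the
column spacing merge into the stronger one. Flood filling then grows each
seed in order of decreasing smoothed intensity — each pixel joins its
brightest already-labelled neighbour — so territories partition the image
watershed-style, stopping below 20% of the seed's peak. The 20% floor and
the watershed tie-handling are implementation decisions; masks are
guaranteed disjoint and connected. Column spacings convert stated fields
of view to pixels: ~38 px for 5 μm medulla columns on a 34 μm / 256 px
field, ~60 px for 4 μm lobula columns on 17 μm / 256 px; both are plain
arguments.

**Responses.** ΔF/F₀ uses a per-trial F₀ from the 1.5 s before stimulus
onset; ROIs with non-positive F₀ are flagged invalid. The response to a
trial is the mean ΔF/F₀ of the two frames immediately after full
expansion (~150 ms apart at 6.83 Hz; the return-to-green event serves
Dm9-like cells whose response outlasts the disc). Responsiveness is the
mean response over reference levels (UV 12–15 for ON, 0–3 for OFF, 0–1
for Dm9-like), and `threshold_sweep()` reports how the aggregate estimate
and fly count evolve as the threshold removes weak ROIs — the stability of
that sweep is itself a test.

**Isoluminance and aggregation.** ON curves are scanned downward from
UV = 15 and OFF curves upward from UV = 0 for the first crossing to
negative, linearly interpolated; with no crossing the level of the
minimum response is returned (`crossing_found = FALSE`), and a curve
already negative at the first scanned level returns that boundary level
capped. Aggregation is strictly two-level — ROIs to fly mean, fly means
to grand mean — so flies with many ROIs do not dominate; the population
isoluminance applies the same scan to the across-fly mean curve.

# Hexagonal-lattice motion model

`hex_sample()` tiles the image with flat-topped hexagons, default
120 px point-to-point by 104 px flat-to-flat (the only orientation in
which those two numbers describe a near-regular hexagon), columns at
pitch 90 px with alternate columns offset 52 px. Pixels are assigned to
the nearest center with a lexicographic tie-break; because the pixel
lattice is invariant under the center-lattice translations (90, 52) and
(0, 104), every interior cell receives exactly
$0.75 \times 120 \times 104 = 9360$ pixels — an identity the tests assert
rather than approximate.

For each site and cardinal direction, the home intensity $I_h$ is the
mean channel-weighted intensity of the site plus its six neighbours, and
the background $I_b$ the mean of the three facets adjacent to the home
group's leading edge along the direction of motion (the neighbourhood
template is read from the geometry of the facet groups and kept
configurable). The directional Weber contrast is
$C = (I_h - I_b) / I_b$; sites missing any facet, or with non-positive
background, are excluded rather than padded. ON motion is the vector sum
of positive contrasts over the four directions, OFF motion the sum of
negative-contrast magnitudes, each computed under its own RGB weight
vector — `(1,0,0)`/`(0,0,1)` gives the red-ON/blue-OFF configuration —
then projected on the site's radial unit vector away from (approach) or
toward (recede) the focus; `combined = on + off`. With equal ON and OFF
weights the recede estimate is exactly the negated approach estimate, so
approach/recede asymmetries arise only through the channel asymmetry and
the asymmetry of the Weber formula itself. Approach–recede comparisons
use a two-sided Wilcoxon rank-sum test across hexagonal pixels, as in
the original analysis of the photograph.

A brute-force per-site oracle (independent loops, distance-based
neighbour search) accompanies the implementation in the test suite and
must agree to $10^{-10}$.

# Synthetic data: what it does and does not emulate

The generators are first-class, tested code; their defaults are the study
conditions.

- **Behavior** (`simulate_behavior`): edge trials carry
  $A\tanh((u - I)/s)$ with $I = I_{ON}$ or $I_{OFF}$; the measurement
  constrains only the zero crossing, not the ΔWBA–contrast transfer
  function, so the sigmoid (slope $s = 2$ UV levels) is an explicit
  artifact choice. Disc trials respond in proportion to
  $\tanh(d/s)$ of the margin $d$ to the nearer visibility boundary, zero
  inside the invisibility band. Mirror trials are exact sign-inverted
  copies; noise is a per-trial Gaussian offset plus per-sample white
  noise (SD `noise_sd` each). Defaults: $I_{ON} = 4.5$, $I_{OFF} = 9.2$
  (the behavioral medians), amplitude 1, noise SD 0.05, 5 trials per
  stimulus per rotation, standard level set {0,2,4,…,12,15} or 3–9
  compact.
- **Movies** (`simulate_movie`): Gaussian blobs (FWHM = one column
  spacing) on a dim uniform baseline (0.2 versus blob amplitude 2,
  emulating a dark-field recording); per-trial response linear in UV with
  the planted zero crossing, filtered by a first-order exponential
  (τ = 0.3 s) emulating indicator kinetics; integer rigid jitter
  (rounded Gaussian, recorded for recovery tests); additive Gaussian
  pixel noise, truncated at zero. Deliberately not modelled: Poisson
  shot noise, photobleaching, non-rigid motion, neuropil contamination,
  realistic indicator nonlinearity. Passing tests therefore demonstrate
  correctness of the analysis logic, not robustness to every property of
  real two-photon data.
- **Images** (`make_test_image`): a flat disc on a flat background. The
  standard configuration, warm disc (200,120,40) on cool background
  (40,120,200), is luminance-balanced — equal unweighted channel mean —
  so the channel-symmetric motion configuration sees an almost exactly
  zero-contrast scene while chromatic configurations see strong
  structure; that is the controlled analogue of a warm fruit against
  foliage.

# Numerical choices and problem sizes

Zero crossings are linear interpolations between adjacent integer levels;
estimator exactness on noiseless piecewise-linear curves is asserted to
$10^{-12}$. Ties at zero resolve as described above. The alignment search
is ±32 px; flood-fill tie-breaks follow descending intensity order.
Validation cohorts in the tests and the acceptance script use 8 simulated
flies × 3 ROIs per polarity at 128 × 128 px with 2 px jitter SD and 0.02
noise SD (planted crossings UV = 5 ON / UV = 8 OFF), 10 behavioral flies
at noise SD 0.1, and a 900 × 1500 px disc image with the full 120 × 104
lattice for the motion model; these sizes recover planted parameters
comfortably within the stated tolerances (±0.3 UV levels imaging, ±0.25
behavioral medians) while keeping a full run in minutes on one CPU.

# Known limitations

- The hexagonal-lattice facet-group template is inferred from geometry
  and exposed as configuration; other plausible "leading edge" choices
  would change per-site contrasts (not the qualitative approach/recede
  asymmetries, which the tests check directionally).
- Border hexagons participate whenever all required facets exist, even if
  their own pixel sets are clipped by the image edge; stricter interior
  filtering is available via the `interior` flag.
- Alignment is rigid and integer-valued by design; sub-pixel or
  non-rigid motion is out of scope.
- The behavioral generator's sigmoid slope and the movie generator's
  response gain are conventions; only zero crossings and orderings are
  treated as meaningful, and only those are asserted.
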