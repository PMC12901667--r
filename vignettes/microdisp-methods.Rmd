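---
title: "Models and methods behind microdisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microdisp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdisp)
```

`microdisp` analyses dispersal assays of *Tetrahymena thermophila* run in
shallow two-patch microcosms, and simulates such assays with known ground
truth. This vignette documents the models, the conventions and the
numerical choices, in the order the pipeline runs them.

## Landscape geometry and zones

A landscape is two 16 × 10 mm habitat patches joined by a 2.5 mm-wide
corridor of length 10 mm ("Short") or 20 mm ("Long"), or a single isolated
patch ("Control"). The canonical frame places the origin at the bottom-left
corner of the Start patch: `x` runs across the patch width (0–10 mm) and
`y` along the dispersal axis, so the Start patch occupies `y ∈ [0, 16)`,
the corridor `y ∈ [16, 16 + L)` within the x-band `[3.75, 6.25)`, and the
Target patch the next 16 mm. Three conventions are deliberate:

- **The corridor is centred** on the patch width. The physical plates fix
  the lateral placement but the analysis only needs a consistent choice;
  centring is the symmetric default.
- **Half-open intervals** everywhere, so every interior point belongs to
  exactly one zone and the partition is testable by Monte Carlo
  (zone areas recovered within 1%).
- **Millimetres are canonical**; the 4 µm/pixel imaging scale is confined
  to the rendering and detection layers.

A position outside the accessible area is rejected as an impossible cell
position rather than silently clamped. The stated 100 µL patch capacity is
inconsistent with the planar dimensions times the 0.8 mm plate depth
(128 µL); the package uses the planar dimensions and ignores volume.

## The snapshot imaging design

Assays are recorded as short bursts, not continuous video: by default one
75-frame burst at 7.5 fps (10 s) every 12 min from t = 24 min to
t = 396 min — 32 imaging cycles. `burst_schedule()` carries this design and
every module receives it explicitly. Trajectories never span bursts;
each burst is tracked independently.

## The synthetic ground-truth generator

`simulate_ground_truth()` emulates what the imaging platform would have
seen. Cells are inoculated uniformly in a disc of radius 2 mm centred at
(5, 1) mm — the end of the Start patch opposite the corridor, matching
inoculation through the plate's entry points, and consistent with the
observation that real populations progress upward from their point of
entry. Each cell draws a fixed speed, area and axis ratio from truncated
normal distributions; movement is the same correlated random walk as the
null model (below). During bursts the walk advances at the frame interval
(1/7.5 s); between bursts it advances with a coarse 1 s step, with the
turning SD scaled by √(dt/dt_ref) so tortuosity is step-size consistent.

Two optional behaviours create "observed-like" populations that depart
from the decision-free null:

- **Strategies.** A `"hump"` strain multiplies speed by 1.3 and turning by
  0.6 while in the corridor (faster, straighter transience) and slows to
  0.8× with more turning in the Target; a `"slope"` strain slows
  monotonically across Start → Corridor → Target (0.85×, then 0.7×). The
  multipliers encode the two empirically described syndrome patterns; their
  exact values are package defaults chosen to give effects of the size seen
  in real strains (tens of percent), not measured constants.
- **Emigration lag.** For the first `emigration_lag_min` minutes the
  Start/Corridor boundary acts as a reflecting wall, emulating the initial
  reluctance to emigrate that real populations display for roughly the
  first two hours. The default strain panel uses lags of 0–150 min, with
  the fastest strain unlagged.

The default five-strain panel spans 105–250 µm/s (panel mean ≈ 155 µm/s,
the cross-strain average reported for this system) with two hump strains,
two slope strains and one patternless strain. All per-strain values beyond
these anchors are synthetic: the panel reproduces the *structure* of the
study design, not any particular strain's measurements.

`detections_from_truth()` stands in for particle analysis on real frames:
per-frame detection with probability `detect_prob`, Gaussian centroid
jitter, multiplicative area jitter, and Poisson false positives living 1–2
frames at uniform positions (the spawn rate is divided by the mean
lifetime 1.5 so the *present* count per frame matches the nominal rate).
The real system's detection noise is not quantified anywhere we can use,
so these defaults are levers for sensitivity tests, not estimates.
`render_frames()` additionally rasterises detections as bright ellipses on
a dark background at 4 µm/pixel for testing the image-level detector.

What the generator deliberately does **not** emulate: photorealistic
darkfield optics, cell division and death, chemical or oxygen gradients,
conspecific interactions (aggregation, U-turns), and overlap of touching
cells in the image. Tests passing on synthetic data therefore validate the
pipeline's arithmetic and its qualitative behaviour, not the biology of
any particular real strain.

## Tracking

`detect_particles()` thresholds each frame, labels 8-connected components
(via EBImage), keeps components whose area lies in the configured size
range, and summarises each as centroid + area + the axes of the
second-moment-equivalent ellipse (with the 1/12 within-pixel variance
term). On a rasterised 50 × 25 µm ellipse the recovered axis ratio is
within 5% and the centroid within a fraction of a pixel.

`link_detections()` performs frame-to-frame assignment under a distance
gate (`max_step_um`, default 80 µm/frame ≈ 600 µm/s at 7.5 fps — above the
fastest strains): among assignments of maximal cardinality it selects the
one minimising total displacement, solved exactly per frame pair with a
Jonker–Volgenant assignment solver on the gate-connected components
(verified in the tests against a brute-force permutation oracle). Tracks
may bridge up to `max_gap` missed frames (default 1), with the gate scaled
by the number of frames elapsed. This is deliberately not a
motion-model tracker (no Kalman prediction, no multi-hypothesis
branching): at these cell densities and frame rates the gated optimal
assignment is exact on separated cells and well-defined in conflicts.

`filter_trajectories()` applies the three standard quality rules — minimum
duration (2 s), minimum gross displacement (20 µm), minimum detection
frequency (0.5 of spanned frames) — and reports per-rule rejection counts.
The published analysis lists its exact thresholds only in supplementary
material unavailable to us; these defaults are declared substitutes,
configurable in `tracking_config()`.

## Traits

Per trajectory: swimming speed is gross displacement over movement
duration; linearity is net over gross displacement; size is the
trajectory-mean area; shape is the ratio of trajectory-mean major to
trajectory-mean minor axis (means first, ratio second, matching
"averaged over each trajectory"). Raw linearity is biased upward for
short-lived trajectories (for tortuous motion net ~ √t while gross ~ t),
so `linearity_duration_corrected()` computes linearity on non-overlapping
4 s sub-windows and averages them; trajectories shorter than the window
fall back to raw linearity with a flag. The original duration correction
is described only in unavailable supplementary material; fixed-window
sub-sampling is this package's substitute and preserves the stated intent
(short- and long-lived trajectories compared on equal footing).

A trajectory's zone is the majority zone of its detections, ties broken
toward the later zone along the dispersal axis (a cell straddling the
Start/Corridor boundary half-and-half is counted as emigrating).
Aggregation is two-stage — trajectory first, then zone × time point — so
every trajectory carries equal weight regardless of how many frames it was
detected on; Corridor and Target time points with fewer than five
trajectories are excluded. `window_average()` restricts to the early phase
(t = 24 min up to the population's time until half dispersal) before
averaging, and `center_by_landscape()` removes plate offsets within
strain × fragmentation groups while preserving group means exactly, for
cross-plate figures.

## The decision-free null model

The null hypothesis is that cells move only according to a fixed
individual speed and random turning: no time trends, no decisions based on
position or conspecifics. `run_null_simulation()` draws each agent's speed
once, with replacement, from an empirical pool (in the intended use,
Control-patch observations); headings receive N(0, σ²) increments with σ
scaled by √(dt/dt_ref); walls reflect specularly. Keeping the speed fixed
for the whole run is the strongest reading of "no adjustment over time",
and it is what produces spatial sorting (below). Snapshots are recorded
every 12 min from t = 12 min — one cycle ahead of real assays, where the
model already places dispersers in the Target patch.

`calibrate_turning_sd()` inverts the monotone map from turning SD to mean
10 s-burst linearity by bisection (open domain, ≥ 2000 replicates, common
random numbers across evaluations), so a strain's observed Control
linearity can be translated into its σ.

Numerical choices:

- **Two-scale stepping** (1 s between bursts, 1/7.5 s within) keeps a
  396 min simulation of 1000 agents to seconds; the √dt turning scaling
  makes the walk's diffusivity invariant to the step size.
- **Specular reflection** conserves agents and admits a uniform stationary
  distribution over the accessible area, which gives a sharp correctness
  check: after long mixing, the fraction of agents outside the Start patch
  must approach the area fraction 185/345 ≈ 0.536 (Short) or
  210/370 ≈ 0.568 (Long). The check is run with a fast test pool
  (600–1000 µm/s) because it probes boundary handling and stationarity,
  and mixing times scale as 1/v²: at biological speeds the walk simply has
  not equilibrated within one assay duration — which is itself worth
  knowing when comparing null outputs at t = 396 min to data.
- The stepper's hot loop is compiled (Rcpp) but consumes R's RNG stream in
  agent order, so results are reproducible under `set.seed()` and verified
  bit-identical to the pure-R reference implementation kept in the package.

### Spatial sorting, and why "no strategy" still differentiates zones

Even without any zone-dependent behaviour, the per-zone *speed
distributions* of the null model differ: faster agents reach the corridor
and Target earlier, so early Target occupants are skewed fast relative to
the pool (the tests verify this with a binomial test on a two-speed pool).
This is spatial sorting — a sampling effect, not plasticity — and it means
per-zone trait distributions are *expected* to differ under the null
whenever individuals vary. Consequently the package's "no spurious
syndrome" checks are formulated on a zero-variance strain (identical true
speeds: per-zone mean speed recovered within 2%), and the type-I control
of the Kolmogorov–Smirnov comparison is verified on samples that are
genuinely identically distributed. Comparing observed zone distributions
against the *null model's* zone distributions — not against flatness — is
the scientifically meaningful contrast, and is exactly what the pipeline
outputs support.

## Dispersal statistics

Abundance in a zone is the mean over a burst's frames of the number of
trajectories present in that zone on each frame. Dispersal rate is
T/(S + C + T); emigration rate is (C + T)/(S + C + T). The dispersal rate
at termination is the median of the five latest values of a landscape's
curve; the time until half dispersal is the first time point at which half
of that median is *strictly* exceeded (the strictness is a declared
convention; results differ only when a rate equals the threshold exactly).
Front and rear of the Start-patch population are the 90% and 10%
quantiles of the Y coordinate, with linear-interpolation quantiles
(`type = 7`), undefined below 10 cells. Zone-pair KS tests are reported
with raw p-values by default, matching per-panel reporting of unadjusted
pairwise comparisons; a Holm adjustment is available but off by default.
LOESS smoothing exists only in the plotting helper and never feeds a
statistic.

## Problem sizes used by the tests

The test-suite and the acceptance script scale the study design down to
desk size — the package's own choice of test conditions: 120–500 cells per
landscape instead of ~1000, 10–20 seeded replicates for direction checks
(Short vs Long half-dispersal timing, the null model's emigration head
start over a lagged population, the corridor speed excess of hump
strains), and 1000 agents for the null-model limits. At these sizes the
qualitative effects being checked are far larger than their Monte Carlo
error.

## Known limitations

- Tracking assumes cells are resolvable: touching cells merge into one
  component, and no re-identification happens across bursts.
- Measured speed is chord-based at frame resolution; a step that reflects
  off a wall is recorded as its chord, slightly shortening measured path
  length for wall-hugging cells (≪ 1% at the default densities).
- The duration-bias correction and the tracking QC thresholds are
  substitutes for unavailable supplementary specifications, and the
  detection-noise defaults are not calibrated to the real instrument.
- The generator shares its movement kernel with the null model; end-to-end
  tests therefore validate the analysis chain, not the realism of the
  kernel itself.
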