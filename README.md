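# microdisp

Simulation and analysis of ciliate dispersal in two-dimensional fragmented
microcosms.

## The problem

Dispersal decomposes into emigration, transience and immigration, and a
central question in dispersal ecology is whether distinct phenotypes
(dispersal *syndromes*) are associated with each phase — and whether those
arise from spatial sorting of pre-existing variation or from plastic
adjustment. Shallow "2D" dispersal plates make this observable for
*Tetrahymena thermophila*: two 16 × 10 mm habitat patches (Start, Target)
joined by a 2.5 mm-wide corridor of 10 mm (Short) or 20 mm (Long), plus an
isolated Control patch, are imaged from above as 75-frame / 10 s bursts at
7.5 fps every 12 min from t = 24 to 396 min, so that abundance, movement
and morphology of every cell can be followed across the whole landscape
throughout a 6.5 h assay.

`microdisp` implements the complete computational pipeline around such
assays for R users — along with a synthetic ground-truth generator so every
stage is testable without any raw imaging data:

- **geometry** — the landscape coordinate system and the coordinate-based
  assignment of positions to zones (Start / Corridor / Target / Control);
- **synthetic data** — ground-truth cell trajectories under the burst
  ("snapshot") imaging design, noisy detection tables, and rendered
  darkfield-like frame stacks (4 µm/pixel);
- **tracking** — particle detection (threshold, connected components,
  moment-equivalent ellipse) and frame-to-frame linking by exact
  minimum-cost bipartite assignment under a distance gate, with the
  standard quality filters (duration, gross displacement, detection
  frequency);
- **traits** — per-trajectory swimming speed (gross displacement over
  duration), path linearity (net / gross displacement, with a fixed-window
  duration-bias correction), cell size and shape; two-stage zone × time
  aggregation with the ≥ 5-trajectory rule and early-phase window averaging;
- **null model** — a decision-free correlated random walk: each agent keeps
  one speed drawn from an empirical pool and turns by N(0, σ²) per step
  (σ scaled by √(dt/dt_ref)), reflecting specularly off walls — the
  baseline against which dispersal *decisions* are inferred;
- **dispersal statistics** — per-zone abundance, dispersal rate
  T/(S + C + T), emigration rate (C + T)/(S + C + T), dispersal at
  termination (median of the five latest values), time until half dispersal
  (first time point strictly exceeding half of termination), expansion
  front/rear (90%/10% Y-quantiles in the Start patch), and two-sample
  Kolmogorov–Smirnov comparisons of trait distributions between zones.

## Worked example

Simulate a "hump"-strategy strain (faster and straighter in the corridor)
in a Short landscape, track it, and recover the dispersal curve and the
zone-wise trait pattern:

```r
library(microdisp)

spec     <- build_default_landscape("Short")
profile  <- strain_profile("D11", speed_mean = 160, strategy = "hump")
schedule <- burst_schedule(first_min = 24, last_min = 120, interval_min = 12)

truth  <- simulate_ground_truth(profile, spec, n_cells = 300, schedule, seed = 42)
det    <- detections_from_truth(truth, detection_noise(detect_prob = 0.95),
                                seed = 43, spec = spec)
linked <- link_detections(det, tracking_config())
kept   <- filter_trajectories(linked, tracking_config())

curves <- dispersal_curves(kept, spec)
term   <- dispersal_at_termination(curves$curve)
time_until_half(curves$curve, term)
#> [1] 60

rec <- trajectory_traits(kept, spec)
agg <- aggregate_zone_traits(rec)
window_average(agg, t_half = 60)[, c("zone", "speed_um_s", "linearity_corrected")]
#>       zone speed_um_s linearity_corrected
#> 1    Start   157.7            0.742
#> 2 Corridor   213.2            0.861
#> 3   Target   141.3            0.667
```

The dispersal rate climbs from 0.014 at t = 24 min to 0.234 at t = 120 min
(`curves$curve`), half of the termination rate is first exceeded at
t = 60 min, and the window-averaged traits show the hump syndrome the
generator encoded: cells cross the corridor ~1.3× faster and markedly
straighter than they move in either patch, then slow below Start-patch
speed after immigration.

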