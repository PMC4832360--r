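# pilitrack

Quantitative analysis of bacterial twitching motility and type IV pilus
(Tfp) retraction forces from calibrated time-lapse microscopy.

Many bacteria move over surfaces by repeatedly extending, attaching and
retracting type IV pili; the retraction motor generates piconewton- to
nanonewton-scale tension. Two standard assays measure this at the
microscope: (1) movies of small chains of cells, from which per-step
**instantaneous velocities** `v_i = ||r_{i+1} − r_i|| · f` (frame rate
`f`) and the motion's orientation relative to the chain's long axis are
extracted; and (2) arrays of flexible micro-pillar force sensors
(PoMPs), where an attached cell deflects a pillar tip that behaves as a
linear spring, so the pulling force is `F = k · ||δ||` with calibrated
stiffness `k` (240 pN/µm by default) and tip deflection `δ`.

pilitrack implements the full measurement chain for both assays:

* **Synthetic assays with exact ground truth** — chains of cocci moving
  with train-like (directed, occasional 30–90° kinks), crabwise
  (perpendicular with reversals), Brownian or static dynamics, and
  pillar arrays deflected by scripted pull events
  (`simulate_chain_movie()`, `simulate_pillar_movie()`); multi-page
  16-bit TIFF + JSON-sidecar I/O.
* **Sub-pixel tracking** — normalized cross-correlation template
  matching with quadratic sub-pixel peak refinement and quality-gated
  template re-acquisition (`track_roi()`, `track_many()`).
* **Motility statistics** — instantaneous velocities, pooled summaries
  with 100 nm/s histograms, moment-based chain pose, axis-relative
  directionality, reversal counts and the MSD exponent
  (`instantaneous_velocities()`, `pool_and_summarize()`,
  `directionality()`).
* **Force inference** — pillar-grid detection, median rest positions,
  spring-law deflection-to-force conversion, pull-event segmentation
  and 25 pN-bin force distributions (`detect_pillars()`,
  `deflection_to_force()`, `segment_pulls()`, `summarize_forces()`).

The two end-to-end pipelines are `run_motility_pipeline()` and
`run_force_pipeline()`; a command-line wrapper with
`simulate` / `motility` / `force` subcommands is installed at
`system.file("cli", "pilitrack", package = "pilitrack")`.

## Worked example

Simulate a wild-type-like chain (694 nm/s, 30 s at 10 Hz, realistic
imaging noise), run the motility pipeline, then resolve a single large
pull on a pillar array:

```r
library(pilitrack)

cfg <- chain_config("train", speed_nm_s = 694, duration_s = 30, seed = 201)
sim <- simulate_chain_movie(cfg, movie_geometry(c(512L, 512L)))
run_motility_pipeline(sim$movie)
#> motility_analysis
#> summary_stats (nm_s): n = 300, mean = 695.6, sd = 161.8, se = 9.341
#>   histogram: 13 bins of width 100 (nm_s), counts sum to 300
#> directionality: 99.7% parallel, 0.0% perpendicular (n = 300 steps)
#>   reversals: 0; MSD exponent alpha = 1.98

ev <- list(scripted_pull(c(1, 1), 2, 8, 720, direction_deg = 225))
pcfg <- pillar_config(grid_shape = c(2L, 2L), pitch_um = 4, events = ev,
                      noise = noise_config(gaussian_sd = 0),
                      duration_s = 12, seed = 1)
psim <- simulate_pillar_movie(pcfg, movie_geometry(c(192L, 192L)))
run_force_pipeline(psim$movie, expected_pitch_um = 4)
#> force_analysis: 4 pillars, k = 240 pN/um, 1 pull events
#> summary_stats (pN): n = 1, mean = 719.9, sd = 0, se = 0
#>   histogram: 29 bins of width 25 (pN), counts sum to 1
```

Reading the output: the tracked chain yields 300 per-step velocity
samples whose pooled mean, 695.6 nm/s, recovers the configured 694 nm/s
to 0.2%; virtually every step is parallel to the chain axis and the MSD
exponent ≈ 2 confirms directed (ballistic) motion. On the pillar side, a
scripted 3 µm deflection at 240 pN/µm is a 720 pN pull; the pipeline
re-detects the grid, tracks the tip and recovers a single event with
peak 719.9 pN.

## Layout

```
R/                  simulators, tracker, motility and force statistics, pipelines
inst/cli/pilitrack  command-line wrapper (Rscript)
scripts/acceptance.R  headline-recovery script (see above)
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette: models, defaults, numerical choices
```
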