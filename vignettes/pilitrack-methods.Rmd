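---
title: "Methods: simulated twitching-motility assays, sub-pixel tracking and pillar-force inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated twitching-motility assays, sub-pixel tracking and pillar-force inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pilitrack quantifies two things from calibrated time-lapse movies of
piliated bacteria: how fast and in which direction chains of cells move
over a surface (twitching motility, driven by cycles of type IV pilus
extension, attachment and retraction), and how much tension the
retracting pili exert on flexible micro-pillar force sensors (PoMPs).
Because the assays it targets are rarely distributed as raw movies, the
package ships a synthetic-movie generator with exact ground truth; every
downstream stage is validated as a parameter-recovery problem against
that truth.

## The synthetic assays

### Chain movies

A chain of `n_cells` cocci (radius `cell_radius_nm`, centres spaced one
diameter apart along the chain axis) is rendered in each frame as a row
of isotropic Gaussian blobs of scale `psf_sigma_nm` on a constant
background — phase-contrast polarity inverted, which preserves the
sub-pixel centroid information that matters for tracking. Four motion
models cover the motility phenotypes seen in retraction-competent and
retraction-deficient strains:

* **train** — directed motion parallel to the chain's long axis. Per
  frame the speed is drawn from `Normal(speed_nm_s, speed_sd_nm_s)`
  clipped at zero; at Poisson-distributed times (`kink_rate_hz`) the
  axis turns abruptly by a uniform 30–90° kink of random sign. The
  chain body rotates with the motion axis.
* **crabwise** — the chain axis stays fixed and motion is perpendicular
  to it, with the travel direction reversing at Poisson
  (`reversal_rate_hz`) times.
* **brownian** — per-coordinate displacements `Normal(0, sqrt(2 D dt))`
  with `D = diffusion_um2_s`; the chain orientation stays fixed
  (rotational diffusion is not modelled).
* **static** — no motion.

The clipped (rather than rejection-sampled) speed draw keeps the length
of the random stream independent of the data, so a `(config, seed)` pair
is bit-reproducible; at the default mean/SD ratios the clip probability
is negligible and the mean speed is unaffected.

Defaults: 4 cells of radius 500 nm; speed SD 150 nm/s; kink rate
0.05 Hz (one to two kinks in a 30 s movie — "occasional"); reversal rate
0.2 Hz; D = 0.05 µm²/s; 30 s duration. The imaging model uses background
100 counts, blob amplitude 100 counts and read-noise SD 5 counts
(peak SNR ≈ 20 — generous but nontrivial), with `psf_sigma_nm = 250`.

The default geometry is 256 × 256 px at 100 nm/px and 10 Hz, sized for
fast tests. A 30 s train-mode run at ~700 nm/s covers ~21 µm, which a
25.6 µm frame cannot contain; the recovery experiments therefore pass
512 × 512 px frames (384 × 384 px for the slower crabwise runs) so
trajectories never hit the border. When a path would leave the frame the
generator clips it (and warns) rather than failing, and the ground truth
logs the clipped positions actually rendered.

### Pillar movies

Micro-pillar tips sit on a regular lattice (pitch 3 µm by default) and
are rendered as the same Gaussian spots. Each scripted pull applies a
force profile `F(t)` — ramp–hold–release (quarter up, half hold, quarter
down) or triangular — along an azimuth; the tip deflects through the
linear spring, `delta(t) = F(t) / k`, with `k = 240` pN/µm by default
(the calibrated stiffness of the polyacrylamide pillars being emulated).
Overlapping events on one pillar sum their force vectors.

When random events are requested, peak forces follow a *floor-shifted*
exponential: `peak = floor + Exp(mean − floor)` with a 30 pN floor.
Measured pull-force distributions are right-skewed and contain only
pulls the assay could resolve (its histogram bin is 25 pN); a plain
exponential with mean ~70 pN would put about 30% of events below that
resolution, and — by the memorylessness of the exponential — the mean of
the *detectable* events would then exceed the nominal mean by the whole
threshold, making mean recovery ill-posed by construction. The shift
keeps the distribution shape while making every scripted event
resolvable. An `exact_mean` option rescales the exponential part so the
sample mean of the scripted peaks hits the requested mean exactly, which
decouples recovery experiments from sampling scatter.

## Tracking

`track_roi()` is template matching by normalized cross-correlation
(zero-mean, unit-variance per window), which is invariant to background
level and illumination drift. The template is the ROI window of frame 1;
each later frame is correlated against a search window centred on the
previous position (default radius 10 px/frame, covering ~700 nm/s motion
at 10 Hz and 100 nm/px with margin). The integer argmax — ties broken
toward the smallest displacement — is refined by separable 1-D quadratic
fits through the 3 × 3 correlation neighbourhood of the peak. Positions
are reported in nm; the per-sample quality is the peak correlation.

Two details matter for accuracy:

* Every frame is registered *to the template*, not to the previous
  frame, so localization errors do not accumulate as a random walk along
  the trajectory; per-step displacements are differences of successive
  positions, consistent with the instantaneous-velocity definition.
* When the peak correlation drops below `refresh_quality` (default 0.5)
  the object's appearance has changed abruptly — in practice, the chain
  rotated at a kink, where a pure fixed or running-average template
  mistracks badly enough to corrupt pooled speed estimates by tens of
  percent. The tracker then re-localizes the object by the
  rotation-invariant thresholded intensity centroid of the search window
  and re-acquires the template there. This is re-acquisition, not
  rotating-template registration; the one-frame re-anchoring offset it
  can introduce is far smaller than the mistracking it prevents.

An exponential running-average template (`alpha = 0.1`) remains
available for slow shape change, but it accumulates drift on long movies
and is off by default. Trajectories are truncated with a warning when
quality stays below `min_quality` (0.2) for more than `max_lost` (5)
consecutive frames, or when the search window no longer fits in the
frame.

## Motility statistics

Instantaneous velocity is the raw frame-to-frame step length times the
frame rate — no smoothing, matching the "instantaneous" definition at
10 Hz. Localization noise inflates raw speeds by roughly
`sigma^2 / step` per step; at the default SNR the per-coordinate error
is a few nm against ~50–70 nm steps, a bias well under the 3% recovery
tolerance, which is why smoothing is not applied (it is also why very
slow motion should be interpreted against the noise floor, not as true
speed). All steps from all chains and replicates are pooled before
mean/SD/SE (n counts steps, not chains), and histograms use left-closed
right-open bins anchored at 0 — 100 nm/s wide for velocities, 25 pN for
forces.

Chain pose comes from intensity moments: centroid plus the principal
eigenvector of the second-moment tensor, with the axis reported modulo
180° (it is undirected). Windows with eigenvalue ratio below 1.2 are
flagged degenerate (an isotropic blob has no axis) and excluded from
directionality. Steps shorter than 20 nm (the localization noise floor)
are likewise excluded from angle statistics. A step is "parallel" at
≤ 30° to the axis and "perpendicular" at ≥ 60°; both thresholds are
package choices — the emulated assays report the qualitative phenotype
only. Reversals are sign changes of the displacement projected on the
dominant motion axis (the principal direction of the step vectors, which
is the parallel component for train-like motion and the perpendicular
one for crabwise motion), counted only when the new sign persists for
≥ 3 steps. The MSD exponent comes from a log-log least-squares fit over
lags up to a quarter of the trajectory, capping estimator variance at
large lags; ≈ 1 indicates diffusion, ≈ 2 directed transport.

## Force inference

The pipeline detects the pillar lattice in frame 1 (local maxima on a
3 × 3 box-smoothed frame above median + 6 MAD — a 3-sigma cut would
admit tens of noise maxima per frame — followed by moment refinement, an
integrated-mass filter at 20% of the brightest spot, and an axis-aligned
lattice fit with residuals required under a quarter pitch). Each tip is
tracked with a 5 px search radius; its rest position is the per-frame
median of its tracked positions, which tolerates transient pulls up to a
50% duty cycle. Deflections convert to scalar forces as
`F = k * ||delta||` (the 2-D norm; pull azimuth is recorded but the
distributions are of scalar force).

Pull events are maximal runs with `F >=` threshold lasting at least 3
frames; runs separated by a single sub-threshold frame are merged, by
two or more kept distinct. The default threshold is
`max(25, 5 * sigma_hat)` pN with `sigma_hat` the MAD-based baseline
noise: 25 pN equals one histogram bin (sub-bin pulls are unresolvable in
that presentation) and the 5-sigma rule keeps the false-event rate on
noise-only series at effectively zero (the suite bounds it at ≤ 0.1
events per 10⁴ frames). The distribution statistic is the event *peak*
force by default; "the force of a transient pull" is ambiguous between
peak and mean, so the event mean is also emitted and selectable.

## Problem sizes and what the tests show

The recovery experiments run at: three 30 s replicate movies per
velocity experiment (301 frames each, 512² or 384² px, pooling 900
steps); one 30 s 8 × 8 pillar movie with 96 scripted pulls of
ground-truth mean exactly 69.9 pN; and one noise-free 2 × 2 pillar movie
with a single 720 pN (3 µm) pull. At these sizes the pooled velocity
recovery lands within 3% of the configured speed, the recovered mean
peak force within 10%, and the large pull above 700 pN — the suite
computes each of these end to end; no result is asserted that the tests
or the acceptance script do not themselves produce.

Passing these experiments shows the *measurement chain* (rendering →
registration → statistics) is unbiased at realistic SNR, motion and
force scales. It does not show that real movies meet the generator's
assumptions: real chains bend and grow, phase-contrast halos are not
Gaussian blobs, illumination drifts, substrates creep, neighbouring
pillars couple elastically, and camera noise is not purely additive
Gaussian. The generator deliberately omits all of these (see
`Non-goals` in the relevant help pages); on real data the tracker's
quality trace and the residual of the lattice fit are the first
diagnostics to inspect.

## Known limitations

* Single-object chain tracking: no data association or occlusion
  handling; two chains crossing will corrupt both trajectories.
* The rigid-chain assumption means per-frame axis estimates are exact in
  simulation but only approximate for bending chains.
* Kink detection is exposed only through the reversal/angle machinery;
  abrupt axis changes smaller than the 30° kink floor are not
  distinguished from curvature.
* Rest-position estimation fails for pillars under tension for most of
  the movie (duty cycle above ~50%).
* Forces are inferred per pillar independently; substrate-mediated
  cross-talk between pillars is not corrected.
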