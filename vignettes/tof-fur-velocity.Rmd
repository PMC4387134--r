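---
title: "Quantifying fur, fur colour and velocity effects on TOF depth imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fur, fur colour and velocity effects on TOF depth imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tofcow)
```

## The problem

Precision-livestock applications — body condition scoring, backfat
estimation, lameness detection from back posture — start from the 3-D
shape of a cow's lower back, and continuous-wave time-of-flight (TOF)
depth cameras are a natural way to capture it from a top view. Two
properties of the recording situation work against the sensor, though:
the animal is covered in fur, which scatters and (if dark) absorbs the
modulated infrared signal, and the animal moves. `tofcow` quantifies
both effects on a controlled stand-in for the animal: two cow-back
models — a homogeneous plaster cast and a fur-covered model with black
and white patches — towed under a fixed camera at 0, 10, 20 and
30 cm/s.

Four criteria carry the analysis:

* **HQIratio** — the fraction `N/C` of recorded frames that pass all
  quality tests at a velocity;
* **SumDiff** — per pixel, the mean absolute depth difference between
  consecutive standstill frames,
  `1/(N0-1) * sum_i |frame_{i+1} - frame_i|`;
* **pwStd** — per pixel, the temporal standard deviation of depth
  across the standstill frames (denominator `N0 - 1`);
* **RpV** — per landmark and velocity, the range of its detected
  X-coordinates divided by the number of usable frames,
  `(max - min)/N`, an imprecision measure.

The original camera streams are proprietary and unavailable, so the
package has two modes. *Fixtures mode* (`fixture_report()`,
`analysis/01_reproduce_tables.R`) recomputes every number that follows
from in-package inputs: the recorded frame counts (`hqi_counts()`) and
the landmark imprecision table (`rpv_table()`). *Simulate mode*
(`run_experiment()`, `analysis/02...05`) runs the same measurement
chain on a synthetic scene generator and checks that the qualitative
structure — directions, orderings, effect directions — reproduces.

## The four-phase measurement model

A continuous-wave TOF pixel estimates the phase delay of the returning
signal from four charge samples `Q1..Q4` gated by control signals 90
degrees apart: `t_d = atan2(Q3 - Q4, Q1 - Q2)` mapped to `[0, 2*pi)`,
and `d = c/(2f) * t_d/(2*pi)`. At the 30 MHz modulation frequency the
unambiguous range `c/(2f)` is 5 m (the camera's stated range; the
nominal `c = 3e8 m/s` makes this exact). `depth_from_phases()` inverts
noiseless phase synthesis to below a nanometre over the calibrated
0.8–5 m range; degenerate charge sets are flagged invalid rather than
raised as errors, as a camera would report a low-confidence pixel.

This model is not decoration: it is what couples motion to image
quality. The four samples are acquired sequentially, so a moving object
is in four slightly different positions within one frame
(`demodulate_moving()`), and pixels whose sub-samples straddle a depth
edge demodulate to a value between the two surfaces — the classic TOF
motion smear.

## The synthetic scene

`surface_spec()` / `build_cow_surface()` define a parametric lower-back
geometry on a superellipse footprint (fur model 0.5 × 0.5 m, plaster
cast 0.55 × 0.56 m): a backbone ridge along the direction of travel, a
tail bump at the posterior end, two ischeal-tuberosity bumps in the
posterior-lateral quadrants and two rump-dish depressions between
backbone and tuberosities. Elevations stay within the models' measured
0.15–0.22 m (plaster 0.16–0.22 m), the crest reaching 0.22 m at the
tuberosities and tail. Ground-truth landmark coordinates are the
analytic bump centres; bumps that would interact (centres closer than
twice the summed widths) are a configuration error rather than a silent
distortion. The fur model carries a binary black/white pattern (two
elliptical white spots, about a fifth of the interior, matching the
recorded animal's proportions) and four 0.05 × 0.05 m, 0.25 m high
corner posts on its mounting board.

Rendering is an orthographic top view on the metric grid the camera
sees at its 1.28 m mount distance: plate pixels measure the mount
distance, model pixels `mount - elevation`. A full pinhole projection
would change nothing the criteria see — the analysis consumes depth
values, not perspective geometry — so it is deliberately left out.

**Noise.** Additive Gaussian depth noise with per-surface-class sigmas;
the defaults are taken from the per-pixel temporal standard deviations
the original recordings showed: 3 mm on plaster, 2 mm on white fur,
6 mm on black fur. A 1-pixel band along steep edges (model rim, beam
outlines) receives a much larger sigma (20 mm), standing in for the
mixed-phase/multipath errors that concentrate there; the band width and
all sigmas are `noise_spec()` parameters.

**Motion artifacts.** Every moving frame carries the deterministic
four-phase smear: the scene is resampled at four sub-frame positions
(the model advances by `velocity/(4*frame_rate)` between control
signals) and re-demodulated per pixel. On top of that, a frame is
*corrupted* with probability `artifact_rate(velocity)`: the pixels
whose sub-samples disagree by more than the ~1 mm noise floor (or saw
different albedo) get their phase scrambled, producing the erratic,
possibly wrapped depth values real streams show along motion edges. In
standstill, a corruption event scrambles a random interior patch
instead — a sporadic interference stand-in for whatever caused the real
standstill recordings to lose a fraction of their frames — since a
motionless four-phase resample is a no-op. The default artifact-rate
tables (plaster 0.13/0.32/0.34/0.38 at 0/10/20/30 cm/s; fur
0/0.66/0.94/0.985) are a *calibration*, chosen so that default
simulations land near the recorded high-quality-image ratios; they are
not derived physics, and the vignette says so deliberately.

**Determinism.** One root seed; each frame's random stream is derived
from `(seed, frame index)`, so streams are bit-reproducible and
insensitive to how many frames preceded them.

## Segmentation and the quality suite

The empty scenery (plate-only frames) is averaged per pixel into a
background model; elevation is `background - frame`, and pixels inside
the configured height band (default 0.02–0.25 m, adapted to the models'
0.22 m maximum) form the candidate mask. Configured beam rectangles are
removed; a rectangle from the model's lower edge to the image's lower
border is temporarily appended so the original body-presence rule (a
cow reaches the lower image border; the models do not) holds, and
removed again after the check — it never contributes pixels to any
criterion. The largest 8-connected component is kept and enclosed holes
are filled. Components use 8-connectivity to match the Moore
neighbourhood of the region partition.

The quality tests the original software applied are cited to prior,
unpublished work, so the suite here is defined by this package and kept
parameterised (`seg_config()`). A frame fails if any of the following
holds: no foreground; foreground area outside 2 000–20 000 px (chosen
so the noiseless fixtures pass and empty or truncated frames fail);
foreground touching the left, right *or top* image border (motion is
vertical, so truncation shows at the top, never left/right; the lower
border is covered by the rectangle rule); a secondary candidate
component of at least 100 px (the floor keeps single-pixel noise
flickers and the ~80 px beam posts out of the rule); more than 1 % of
foreground depths outside the calibrated range *or implying elevations
outside the height band* — the "adapted tolerances" reading of the
range rule, and the channel through which phase-scrambled pixels,
hole-filled back into the mask, make corrupted frames fail; and any
required landmark undefined. All failures are enumerated, not just the
first.

As a robustness control, the entire analysis can be re-run on frames
mirrored about the vertical midline between columns 72 and 73
(`mirror_frame()`, `experiment_config(mirror = TRUE)`); all comparative
conclusions must be identical up to left/right relabeling, which the
test suite asserts.

## Regions, fur colours, landmarks

A foreground pixel whose radius-1 Moore neighbourhood intersects the
background is *boundary*; otherwise *interior* (`partition_regions()`;
the image border counts as background). "Radius one" on a square grid
is read as the 8-neighbourhood; the observed 1–2 px band width on the
synthetic masks supports that choice. Interior pixels of the fur model
split at amplitude gray value ≥ 25 into white and black
(`fur_color_mask()`); the simulator renders amplitudes on 0–255
directly (white fur/plaster high, black fur low), and 16-bit external
input is min-max scaled per stream before thresholding, since the
original conversion is not documented.

The landmark detector is an intentionally simple geometric surrogate
for the unpublished body-trait software; RpV is defined over whatever
detector is plugged in. Design, in order: the elevation map is 3×3
median filtered (single-pixel spikes in the heavy-noise boundary band
otherwise capture the extrema searches); the backbone trace is the
per-row elevation argmax within the central third of the model's
columns, median-smoothed over 5 rows; the tail is the posterior end of
the trace, its column the median of the last five trace columns; the
tuberosities are the elevation maxima of the posterior-lateral
quadrants, restricted to the interior core (two erosions off the band)
and reported as the centroid of the 2 mm summit plateau — markedly
stabler than a raw argmax under noise; the dishes are the corresponding
minima between backbone and each tuberosity; BB30 is the trace point
whose Euclidean distance to the tail is closest to 30 px, ties broken
toward the anterior. Every landmark has an "undefined" escape
(featureless surface, missing prominence — 15 mm for tuberosities, 8 mm
for dishes — empty search region, trace of ≤ 30 rows) instead of an
error. With default noise the detected X-coordinates fluctuate by at
most 2 px across standstill frames, matching the 1–2 px the original
software showed.

## Criteria, fits, statistics

SumDiff and pwStd are computed on the pixels that are foreground in
*every* standstill frame (`common_foreground()`), so consecutive-frame
differences always compare model surface with model surface; pixels
that jitter in and out of the mask belong to the boundary band in
spirit. Whether the original computation intersected masks per pair or
across all frames is not stated; the choice is exposed as
`mask_mode = "per_frame"` for the other reading. All depths are meters
throughout. Two exact identities pin the implementations: for two
frames `SumDiff = sqrt(2) * pwStd` pixel-wise, and pwStd is invariant
under any frame permutation.

Velocity fits use the *ordinal* abscissae x = 1, 2, 3, 4 for 0, 10, 20,
30 cm/s — not the cm/s values. Only this encoding reproduces the
reported coefficients (the plaster quadratic `0.037x^2 - 0.261x +
1.087` evaluated at x = 1 gives the standstill ratio 0.87) and
goodness-of-fit values. Fits consume the unrounded ratios `N/C`; from
the two-decimal table values the plaster quadratic coefficient would
come out 0.0375 instead of the reported 0.0368. Goodness of fit follows
the curve-fitting-toolbox convention `RMSD = sqrt(SSE/dof)` with
`dof = n - p` (a single degree of freedom for four points and three
parameters) and `R^2 = 1 - SSE/SST`.

The Gaussian-exponential model is implemented as
`K * exp(-((x - L)/M)^2)` — with a *negative* sign in the exponent,
although the fur equation is printed with a positive one: only the
decaying form reproduces the fur ratios (0.9998 at x = 1, 0.342 at
x = 2) and the reported RMSD 0.0095. For monotone, log-convex data such
as the plaster ratios the model is degenerate: the optimum runs along a
ridge of growing `|L|` and `M` toward a pure exponential, which is why
the reported plaster parameters look absurd (`K ~ 1e30`, `L ~ -1252`)
while RMSD 0.078 and R² 0.83 are perfectly stable. The fitter is a
deterministic multi-start (default start `K = max(y)`, `L` at the
argmax, `M` the grid span; a log-quadratic start that is exact on-model;
log-linear ridge starts at several `M`; each polished by Nelder-Mead
then BFGS), keeping the global SSE minimum; twenty random restarts
reproduce the fur minimum to 1e-6.

Group comparisons use Wilcoxon rank-sum tests with midranks. For small
groups (min size ≤ 8 within an enumeration budget) the permutation
distribution of the rank sum is enumerated exactly — unlike classical
exact tables this stays exact under ties; otherwise the normal
approximation with tie and continuity correction is used (it matches
`wilcox.test`'s to machine precision, and is within 0.02 of enumeration
for continuous samples of sizes 5–8, while heavily tied tiny samples
are precisely why the exact path exists). Effect sizes are rank-based
`eta^2 = SS_between/SS_total` on midranks, identical to
Kruskal-Wallis `H/(n-1)`; both are invariant under strictly monotone
transforms.

Two tabulation conventions matter for reproducing the printed numbers.
Reported values round half *away from zero* (`round_half_away()`:
-0.005 prints as -0.01), and the reported medians of the RpV quadratic
coefficients are medians of the *2-decimal-rounded* coefficients — the
plaster median -0.005 is only reproducible that way (the unrounded
median is -0.004125). One reported effect size resists reproduction on
principle: the very large model effect on the RpV coefficients is
printed as eta² = 0.846, but the twelve coefficients separate the two
models completely, and complete separation of 6 vs 6 ranks caps
rank-based eta² at 108/143 ≈ 0.755, which is what the package reports.
Whatever produced 0.846 was not eta² on midranks of these twelve
values; the implementation does not tune toward it.

## Problem sizes, runtime, limitations

Fixtures mode touches no random state and runs in well under a second.
The analysis scripts simulate 60 s of standstill at 9 fps and five
passes per moving velocity (moving passes at the sensor's higher 36 fps
effective rate, so the fur arm keeps a handful of usable frames at
30 cm/s, as the original campaign did; the achieved recording rate is
not documented and is a free parameter here). The test suite's
simulation-based checks use 40–2000-frame streams chosen so each
property is measured with adequate power; the full suite runs in a few
minutes on one CPU.

What passing simulations do and do not show: the generator reproduces
the *mechanisms* — class-dependent noise, a heavy-noise edge band,
four-phase motion smear, velocity-dependent frame corruption — and the
pipeline recovers the directions and orderings the real data showed
(boundary ≫ interior, black ≫ white, fur arm collapsing with velocity,
near-linear plaster RpV vs fast-growing fur RpV). It does not emulate
real fur microstructure, true multipath optics, lens distortion,
integration-time control, sunlight or insects (the original recordings
were taken indoors to exclude the latter two), and its artifact rates
are calibrated, not predicted. Agreement of simulated medians with the
recorded ones to the first significant digit is a consequence of taking
the noise sigmas from the recorded medians, not an independent
validation of them.
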