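# tofcow

Quality metrics for continuous-wave time-of-flight (TOF) depth imaging
of cow-back models — for researchers in precision livestock monitoring
who need to know how much fur, fur colour and animal movement degrade a
top-view depth stream before trusting body-shape traits extracted from
it.

A TOF pixel measures distance through the phase delay of modulated
infrared light, estimated from four gated charge samples:
`t_d = atan2(Q3 − Q4, Q1 − Q2)`, `d = c/(2f) · t_d/(2π)`. Fur scatters
and absorbs that signal (black fur far more than white), and because the
four samples are sequential, object motion smears and corrupts the
estimate. The package quantifies these effects on two physical stand-ins
for a cow's lower back — a homogeneous plaster cast and a fur-covered
model — moved at 0, 10, 20 and 30 cm/s, using four criteria:

* `HQIratio = N/C` — fraction of recorded frames passing all quality
  tests at a velocity;
* `SumDiff = 1/(N₀−1) · Σᵢ |imageᵢ₊₁ − imageᵢ|` — per-pixel mean
  absolute consecutive difference over the standstill stream;
* `pwStd` — per-pixel temporal standard deviation over the standstill
  stream;
* `RpV = (max X − min X)/N` — range of a landmark's detected
  X-coordinates per usable frame, an imprecision measure.

Velocity trends are summarised by least-squares fits of the four-point
criterion vectors over the ordinal velocity grid x = 1..4: quadratic
`α·x² + β·x + γ` and Gaussian-exponential `K·exp(−((x−L)/M)²)`, with
`RMSD = √(SSE/dof)` and `R²` as goodness of fit. Group contrasts
(boundary vs interior pixels, black vs white fur, model vs model) use
Wilcoxon rank-sum tests — exactly enumerated for small groups, ties
included — with rank-based `η² = SS_between/SS_total` effect sizes.

The original SwissRanger recordings are proprietary and unavailable, so
the package embeds the experiment's frame bookkeeping and imprecision
tables as fixtures, and provides a synthetic four-phase TOF scene
simulator (surface geometry with tail/tuberosity/dish/backbone
landmarks, class-dependent noise, boundary-band noise, motion smear and
corruption) for end-to-end runs of the full pipeline: empty-scenery
background subtraction, segmentation with quality tests, region and
fur-colour partitioning, landmark detection, criteria, fits and tests.

## Worked example

Recompute the headline results from the embedded recording counts:

```r
library(tofcow)
rep <- fixture_report()
rep$table1[rep$table1$model == "fur", ]
#>   model velocity    C    N        hqi
#> 5   fur        0 2138 2138 1.00000000
#> 6   fur       10  411  141 0.34306569
#> 7   fur       20  356   21 0.05898876
#> 8   fur       30  267    4 0.01498127
rep$hqi_fits$fur$gaussian
#> gaussian_exp fit: K = 1.545, L = -0.1611, M = 1.761
#>   SSE 9.10945e-05, RMSD 0.0095, R^2 0.9999, dof 1
rep$hqi_fits$plaster$quadratic
#> quadratic fit: alpha = 0.03679, beta = -0.2605, gamma = 1.087
#>   SSE 0.00187044, RMSD 0.0432, R^2 0.9489, dof 1
rep$alpha_ratio
#> [1] 4.164888
```

Reading: the fur arm keeps every standstill frame (ratio 1.00) but
collapses to 1.5 % usable frames at 30 cm/s, and its decay is captured
by the Gaussian exponential with RMSD 0.0095; the plaster arm's decay is
mild and quadratic. The quotient of the quadratic coefficients, ≈ 4.16,
is the headline number: image quality falls about four times faster with
fur than without.

`rep$table4` refits the landmark-imprecision vectors: plaster
coefficients hover at zero (linear growth of imprecision) while fur
coefficients reach 1.15; their medians are −0.005 vs 0.41 and the
between-model rank-sum test gives p = 0.0022 with rank-η² = 0.755.

The simulation side runs the same chain on synthetic streams:

```r
cfg <- experiment_config(seed = 1, standstill_duration = 30, passes = 2)
bundle <- run_experiment(cfg)   # table1, pixelwise medians, tests, RpV
```

## The analysis workflow

Numbered drivers under `analysis/` (each prints what it finds and writes
tables under `results/`; bulky frame containers go to `scratch/`):

1. `01_reproduce_tables.R` — fixtures mode: ratios, fits, quotient,
   RpV refits, coefficient test.
2. `02_simulate_streams.R` — simulate both arms at all velocities plus
   the empty scenery; write stream containers and sample PGM frames.
3. `03_quality_ratios.R` — ingest containers, segment, apply quality
   tests, tabulate simulated HQIratios and their fits.
4. `04_pixelwise_criteria.R` — SumDiff/pwStd by region and fur colour
   with rank tests.
5. `05_landmark_precision.R` — RpV per landmark and velocity with
   quadratic fits and the between-model test.

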