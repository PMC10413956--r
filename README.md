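# pathseg

Path segmentation and habitat-use analysis for sympatric foragers.

## The problem

How do two co-occurring predators share the same prey base in the same
habitat?  One productive answer comes from *fine-scale movement paths*:
a visually hunting, sit-and-wait forager and a chemosensory, widely
searching forager leave measurably different trails even when they walk
the same ground.  The classic field design records a focal animal for 30
minutes, marking its location every minute, and scores each marker as
in the open or in vegetation (with the plant species), together with
whether the next marker was visible at ground level from the current
one.

`pathseg` implements the full analysis chain for such data, plus a
seeded simulator so every stage can be exercised, tested, and calibrated
without field data.

## The metrics and statistics

For an observation with fixes at 1-min intervals, the per-interval
**step** has length equal to the straight-line distance between
consecutive fixes.  Intervals without movement are excluded from the
step-length and turn-angle series but kept in the denominator of the
*proportion of intervals with movement*.  For a complete (31-fix)
observation:

- **path length** `L = Σᵢ lᵢ` (sum of all step lengths),
- **net displacement** `D` = distance from first to last fix,
- **straightness index** `S = D / L ∈ [0, 1]`,
- **turn angle** = change in heading between consecutive movement
  steps, signed in (−180°, 180°] or folded to [0°, 180°],
- **visibility index** = proportion of transitions whose destination
  was visible from the origin.

Turn angles are analysed with circular statistics: the mean resultant
length `R = ‖(mean cos θ, mean sin θ)‖`, Rayleigh's uniformity test
`z = nR²`, and a von Mises fit with `κ` obtained by inverting the
Bessel-function ratio `A(κ) = I₁(κ)/I₀(κ) = R`, checked for conformity
with Watson's U² statistic.  Species are compared with Mann–Whitney U
tests (unreduced U convention), two-sample Kolmogorov–Smirnov tests,
R×C chi-squares for habitat/visibility/plant use, a two-proportion z
test for movement frequency, and Pearson correlations between turn
angle and step length.  Within-species step-length variation is
modelled with a random-intercept (per individual) linear mixed model
with sex, snout–vent length, air temperature and wind speed as fixed
effects, and an observer-effect GLM regresses movement responses on
the minute index.

The simulator is a correlated random walk over a square arena with
circular vegetation patches: per-minute movement with probability
`p_move`, lognormal step lengths, von Mises turns with optional
turn-sign persistence, and a cover bias that steers open-ground animals
toward bushes.  Habitat labels come from exact point-in-disc tests and
visibility flags from closed-form segment–disc line of sight.

## Worked example

```r
library(pathseg)

cfg     <- simulation_config(n_visual = 20, n_chemosensory = 20,
                             master_seed = 7)
dataset <- generate_dataset(cfg)
dataset
#> Fix dataset: 40 observations (chemosensory: 20, visual: 20)
#>   complete (31-fix) observations: 35; fixes total: 1189

report <- run_full_analysis(dataset, run_config())
report
```

```
==== Movement and habitat-use analysis ====
Species: visual vs chemosensory | observations: 40 | pooling: pooled

-- Movement metrics, median (range) --
visual:
  step_length            2.055 (0.10-47.02)  n = 248
  path_length           44.942 (15.23-80.62)  n = 16
  net_displacement      19.029 (2.20-47.34)  n = 16
  straightness_index     0.440 (0.04-0.79)  n = 16
  turn_angle            55.482 (0.02-177.54)  n = 228
chemosensory:
  step_length            4.115 (0.49-39.26)  n = 456
  path_length          119.576 (66.28-173.49)  n = 19
  net_displacement      24.520 (12.20-70.03)  n = 19
  straightness_index     0.241 (0.09-0.49)  n = 19
  turn_angle            62.627 (0.21-179.19)  n = 436

-- Between-species comparisons (Mann-Whitney) --
  step_length         U = 31006.0, p = 3.86e-23
  path_length         U = 2.0, p = 7.405e-07
  net_displacement    U = 101.0, p = 0.09448
  straightness_index  U = 256.0, p = 0.0006098
  turn_angle          U = 46042.0, p = 0.1188
  KS step_length      D = 0.374, p = 5.872e-20
  KS turn_angle       D = 0.091, p = 0.1714
  moving intervals: 44.8% vs 76.5%, z = -11.01, p = 3.464e-28

-- Circular statistics on turn angles --
  visual: R = 0.378, Rayleigh z = 32.58 (n = 228), p = 2.981e-15, kappa = 0.817
  chemosensory: R = 0.273, Rayleigh z = 32.38 (n = 436), p = 4.957e-15, kappa = 0.567

-- Habitat use --
  cover       chi2 = 22.6, df = 1, p = 2.043e-06
  visibility  chi2 = 44.1, df = 1, p = 3.108e-11
  plant       chi2 = 16.7, df = 5, p = 0.005152

No multiple-testing adjustment is applied; 17 tests were performed.
```

Reading it: the visual forager moved in 45% of intervals against 77%
for the chemosensory forager, with half the median step length, much
straighter paths (0.44 vs 0.24), comparable net displacement, and more
time in the open — the movement signature of a stalking visual hunter
beside a bush-to-bush chemosensory searcher.  `export_report(report,
"out/", dataset)` writes the CSV tables, 45°-binned turn-angle and 2
m-binned step-length histogram data, a markdown summary, and a JSON
provenance block.

Your own data enter through `read_fixes_csv()` (one row per fix;
columns `observation_id, lizard_id, species, sex, svl_mm, mass_g,
t_min, x_m, y_m, habitat, plant_species, visible_from_previous,
air_temp_c, wind_speed_ms`; absent values empty).  Analysis options —
movement threshold, pooled vs per-individual comparisons, signed vs
folded angles for the circular tests, mixed-model transform and df
method — live in `run_config()` or a YAML file via `read_run_config()`.

A command-line interface wraps the same functions:

```sh
exec/pathseg simulate --preset paper-like --n-visual 61 --n-chemo 51 \
    --seed 1 --out fixes.csv
exec/pathseg analyze --in fixes.csv --out report/
exec/pathseg selfcheck
```

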