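---
title: "Movement-path segmentation and habitat use: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-path segmentation and habitat use: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathseg)
```

`pathseg` analyses 30-minute focal observations of foraging animals
sampled at 1-minute intervals, and ships a seeded generator that stands
in for field data.  This vignette is the package's own account of the
science: the measurement model, the statistical machinery and its
assumptions, the tunable parameters and why their defaults are what
they are, what the simulator does and does not emulate, and the places
where a genuinely open design choice had to be made.

## The measurement model

A *fix* is the animal's position at one minute mark; a full observation
is 31 fixes (t = 0..30).  Consecutive fixes bound a *step*.  The core
convention, from which everything else follows, is:

* An interval whose displacement does not exceed `move_epsilon` is a
  *non-movement interval*.  It is excluded from the step-length and
  turn-angle series, but it stays in the denominator of the proportion
  of intervals with movement and contributes zero to path length.
* `move_epsilon` defaults to 0 m: any nonzero recorded displacement is
  movement.  Field protocols of this type resolve steps of a few
  centimetres, so imposing a coarser threshold would silently discard
  real movement; the option exists (`run_config(move_epsilon = )`) for
  noisier data.
* Whole-path metrics — path length, net displacement, straightness —
  are reported only for complete 31-fix observations.  A truncated
  observation still contributes its step lengths and turn angles to
  pooled analyses.  This keeps whole-path metrics comparable (they
  scale with duration) while wasting no per-step information.
* The straightness index of a path with zero length is reported as
  missing, not 0 or 1: an animal that never moved has no path shape.

**Turn angles across pauses.**  A turn angle is the change in heading
between consecutive *movement* steps.  When a pause separates two
moving steps, the heading is carried across the pause by default: the
turn compares the new step's heading with the last moving step's
heading.  The alternative — dropping any turn that spans a pause — is
available (`across_pauses = FALSE`) because field descriptions of this
protocol do not pin the choice down.  Carrying the heading uses more of
the data and treats a pause as what it is behaviourally (the animal
stands still; its orientation does not reset).

Headings are measured in degrees counterclockwise from the +x axis.
The convention is invisible in every reported quantity: the test suite
verifies that turn angles are invariant under rotation and translation
of the coordinate frame and that signed angles negate under reflection.

## Circular statistics

Signed turn angles in (−180°, 180°] feed the circular machinery;
medians, Kolmogorov–Smirnov comparisons and histograms use folded
angles in [0°, 180°], matching how such results are conventionally
tabulated.  Whether the *circular* tests should see signed or folded
angles is genuinely ambiguous in the field literature, so
`run_config(circular_angles = )` exposes both; signed is the default
because folding discards the left/right symmetry information the von
Mises model describes.

* Mean resultant length `R` and mean angle are the first trigonometric
  moment.
* Rayleigh's uniformity test uses `z = nR²` with the standard series
  approximation for the p-value, clamped to [0, 1].  Published reports
  of this test sometimes print a "df" whose meaning is not defined;
  the result object therefore carries both `n` and `n − 1`, and `z`
  always uses `n`.
* The von Mises concentration is estimated by inverting
  `A(κ) = I₁(κ)/I₀(κ) = R` with bisection to `|A(κ) − R| < 1e−10`,
  capped at κ = 1000 (an `R` numerically 1 means every angle is
  identical; the cap is flagged with a warning).
* Conformity to the fitted von Mises distribution uses Watson's U²
  with both parameters estimated.  Critical values for this case
  depend on κ; the package tabulates them by Monte Carlo (20,000
  replicates of n = 500 per κ row at κ = 0, 0.5, 1, 1.5, 2, 4, 20,
  upper-tail levels 0.10/0.05/0.025/0.01, linear interpolation in κ̂).
  Because only a table is available, the result is honestly reported
  as a p-value *range* bracketed by the tabulated levels, not a point
  p-value.

## Group comparisons

The comparison statistics are implemented from their defining formulas
and cross-checked in the test suite against brute-force oracles (the
O(n²) pairwise count for U, the pooled-ECDF supremum for D) and against
the base-R implementations:

* **Mann–Whitney U** — normal approximation with tie-corrected
  variance and continuity correction at all n, which is standard
  practice at the sample sizes of pooled fix-level analyses.  The
  reported U is the unreduced `U1` of the first-named sample; both
  `U1` and `U2` are returned.
* **Two-sample KS** — asymptotic Kolmogorov p with effective n
  `n₁n₂/(n₁+n₂)`.
* **Chi-square** on R×C count tables, with a warning when any expected
  count falls below 5.
* **Two-proportion z** (pooled variance) and **Pearson correlation**
  (p from the t transform).

**Pooling and pseudo-replication.**  Fix-level analyses (step lengths,
turn angles, habitat fixes) pool measurements by species, treating
fixes as independent.  This matches how such field comparisons are
usually run and reported, but repeated measures from one individual are
not independent, so pooled tests overstate their evidence.
`run_config(pooling = "per_individual")` re-runs the between-species
comparisons on one value per observation (median step length, median
folded turn angle, per-observation open fraction and visibility
index).  The end-to-end calibration test requires the per-individual
mode to hold its nominal size under the null; the pooled mode is not
expected to.  No multiple-testing adjustment is applied anywhere; the
report footer states the number of tests performed.

One caveat is inherited from the study design this mirrors: a
habitat-use chi-square with three habitat categories appears in the
field literature while only open vs vegetation are defined; the
package computes the generic R×C test on the two recordable categories
and documents the discrepancy rather than inventing a third.

## Regression stages

**Step-length mixed model.**  Within-species step-length variation is
modelled as a linear mixed model with a random intercept per individual
and fixed effects sex, snout–vent length, air temperature and wind
speed (the weather at the minute starting each moving interval), fitted
by REML via `lme4`.  Records with a missing covariate are dropped
listwise and counted.  The response is untransformed by default; a log
option exists because step lengths are strongly right-skewed, and no
transform is claimed by the protocols this mirrors.

Each fixed effect is reported as `F = t²` with numerator df 1.  The
denominator df is the genuinely open choice: published denominator df
for this design are not derivable from any single standard rule.  The
default is a containment rule — effects constant within individuals
(intercept, sex, SVL) use `n_individuals − q_b` where `q_b` counts the
between-individual columns; within-individual effects (weather) use
`n_records − n_individuals − q_w` — and the method used is printed in
the result.  Satterthwaite df via `lmerTest` are one option away.  A
fit with zero individual variance is returned with a singularity flag,
not an error, and reproduces OLS estimates.

**Observer-effect trend.**  A pooled least-squares regression of the
response (moving-step length, or folded turn angle) on the minute
index, F-tested with df (1, n − 2).  A flat trend is consistent with
the animals not reacting to the observers' presence over the
observation.  Whether such a check should pool across individuals or
model them is unstated in the protocols; pooled is implemented, and
per-observation diagnostics can be built from `summarize_dataset()`.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:
two species of correlated-random-walk foragers on a square arena with
circular vegetation patches.

Per minute, an animal moves with probability `p_move`; a moving animal
draws a lognormal step length and a von Mises(0, κ) signed turn.  An
animal in the open steers toward a bush with probability `cover_bias`:
the heading becomes the direction to a target patch (chosen among
patches 5 m to `sense_range_m` away, weighted by plant preference and
closeness) plus concentrated aiming noise (κ_steer = 20), the step
stops at the patch rather than overshooting, and the target persists
until cover is reached.  Arena boundaries reflect; after a reflected
move, the realised displacement direction becomes the new heading.
Habitat labels come from exact point-in-disc tests; visibility flags
from closed-form segment–disc intersection, with discs containing
either endpoint transparent (an animal at the edge of a bush sights
out of its own bush, as a ground-level sighting over the marker
itself would).

**Turn-sign persistence.**  Independent symmetric turns make path
straightness a function of `R` and the number of steps alone, which is
too rigid to span the straightness contrasts real foragers show at a
given turn-angle distribution.  The walk therefore draws the *sign* of
each unsteered turn from a two-state chain: with probability
`turn_sign_persistence` the previous sign repeats.  Because the von
Mises magnitude is symmetric and the sign chain is balanced, the
marginal turn-angle distribution — and with it `R`, the Rayleigh
statistic and the fitted κ — is unchanged; only the path's tortuosity
moves.  Values above 0.5 give looping, area-restricted search; below
0.5, a course-keeping zig-zag.

**Shipped presets.**  Two presets encode the contrast between a
sit-and-wait visual hunter and a widely ranging chemosensory searcher:

| parameter | visual | chemosensory |
|---|---|---|
| movement probability / min | 0.44 | 0.75 |
| median step (m) | 2.1 | 4.2 |
| lognormal σ (log m) | 0.95 | 0.75 |
| κ (turn concentration) | 0.72 (R ≈ 0.34) | 0.585 (R ≈ 0.28) |
| cover bias | 0.1 | 0.5 |
| turn-sign persistence | 0.25 | 0.85 |
| sensing range (m) | 20 | 14 |
| start in open | yes | no |
| plant preference | greasewood-dominated | sage ≈ greasewood |

The movement probabilities, step medians and turn concentrations are
the calibration anchors; the lognormal σ values are set so the extreme
step lengths over a pooled sample of several hundred moving steps reach
the tens of metres while medians stay at 2–4 m; persistence, sensing
range and aiming noise are structural choices fixed so that the presets
reproduce the *qualitative* contrasts (the visual forager moves less,
in shorter and straighter paths, more in the open, with higher
visibility) without disturbing the anchors.  These are not claims to
reproduce any particular field dataset.

The arena is 150 m with ~15% vegetated cover (patch radii lognormal,
median 1.2 m) — the cover fraction is a free choice exposed in
`simulation_config()`, since desert-scrub sites vary; 15% open-desert
shrub cover is typical.  Weather is a slow random walk shared by all
observations at matching minutes.  Observations are truncated with
probability 0.15 to a uniform 10–30 fixes, mirroring the fact that
some field observations end early.  Every draw derives from the master
seed through a fixed counter scheme (`derive_seed(master, stream,
index)`), so a dataset is a pure function of its configuration.

**What the generator does not emulate** — and hence what passing tests
do and do not show about real data: shrubs are discs, not irregular
canopies; there is no prey field, thermoregulation, social interaction
or predator avoidance; step lengths are i.i.d. lognormal within a
species rather than individually variable (the mixed model's individual
variance is therefore near zero on synthetic data, and its parameter
recovery is tested on purpose-built simulations instead); weather
covariates influence nothing, so regression stages on synthetic data
test machinery, not effects.  Real straightness values reach higher
(out-and-back commutes, boundary-following) than a correlated random
walk of matched `R` can; the presets reproduce the ordering and
rough magnitude of the species contrast, not its exact size.

## Numerical choices

* Degrees at every exported boundary, radians internally; angles wrap
  to (−180°, 180°] with 180° chosen at the branch cut.
* Straightness is clamped to [0, 1] against rounding; path-length
  identity holds to 1e−9 relative.
* κ bisection: tolerance 1e−10, cap 1000; the von Mises CDF for the
  GOF test is trapezoidal quadrature on a 4096-point grid.
* CSV numerics are written with 17 significant digits, so write→read
  round trips reproduce every double exactly and repeated writes are
  byte-identical.
* The Mann–Whitney normal approximation is used at all n (an exact
  method below n = 20 was considered and rejected: no pooled analysis
  in this design is that small, and the approximation keeps the
  reported convention uniform).
* Simulation sizes in the test suite: metric identities on 1,000
  observations; Rayleigh size at 5,000 replicates; line-of-sight
  against 1-cm brute force on 10,000 random cases; preset recovery at
  100 observations per preset; mixed-model recovery over 200 seeds of
  50 individuals × 20 records, with 2,000 null replicates at 40 × 8;
  end-to-end contrast over 100 seeded runs of 50 + 50 observations and
  200 null-calibration replicates.  These sizes give the property
  checks enough resolution that the stated tolerance, not sampling
  noise, is the binding constraint.

## Known limitations

* The visibility index on real data reflects observer sightings; the
  simulator's geometric line of sight is an idealisation of that
  protocol.
* The containment df rule is one defensible choice among several; df
  for mixed-model F tests are approximate by nature, and the package
  makes the method explicit rather than claiming exactness.
* Watson U² p-values are ranges, not points, by construction of the
  tabulated critical values.
* Time steps must be regular 1-minute intervals; gaps inside an
  observation are permitted by the schema (strictly increasing t) but
  steps spanning a gap are treated like any other interval, which
  understates speed across the gap.  Validation flags rather than
  repairs such records.
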