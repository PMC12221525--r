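---
title: "Methods: larval thermotaxis analysis and the cross-inhibition agent model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: larval thermotaxis analysis and the cross-inhibition agent model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Drosophila larvae regulate body temperature behaviourally: they crawl up
or down thermal gradients, and species adapted to different climates
prefer different temperatures. The assay this package analyses places
larvae on a 170 x 170 mm arena holding a patchy 17-25 °C gradient (four
Peltier-driven temperature sources under an agarose sheet) and records
their positions at 10 Hz for 20 minutes, together with thermal-camera
images of the gradient at 3 frames per minute. From those recordings the
pipeline derives (i) a temperature-preference profile per larva, (ii)
fine-scale navigation metrics, and (iii) species-level fits of a
mechanistic thermotaxis model, followed by phylogenetic comparative
post-processing of the fitted preferences.

Raw video-tracking data for such a study are bulky and rarely
redistributable, so the package ships a synthetic-data generator
(`synth_config()`, `make_thermal_frames()`, `make_tracks()`) that
emulates the assay — including its artefacts — with known ground truth.
Every downstream stage is exercised against that generator.

## The preference index and its null model

Occupancy is tallied in 1 °C temperature windows advanced in 0.1 °C
steps (window starts 17.0-24.0 °C; 71 windows). Because the gradient is
patchy, windows are unequally available, so raw occupancy is scored
against the occupancy of randomly moving agents — an electivity-style
index in the tradition of Ivlev:

$$Tp_w = \frac{t^{obs}_w - t^{null}_w}{t^{obs}_w + t^{null}_w} \in [-1, 1].$$

The null cohort (`simulate_null_agents()`) walks at the run's mean
larval speed, turning as a Poisson process at the run's mean accepted
head-sweep rate with wrapped-normal heading changes (σ = 60° by
default; the source assay reports only speed and turn rate, so the
spread is a package choice, exposed in the arguments). Agents start
uniformly in the centred square covering 33% of the arena side — where
larvae are deposited — and the first two minutes are discarded as
burn-in, as for real larvae.

Windows with zero occupancy in *both* observed and null data are set to
0 rather than −1: they carry no evidence either way. Windows a larva
simply never visited score −1, which biases per-larva profiles
negatively; this bias is inherent to the index (one larva can only be
in one window at a time) and is why cohort-level statements in the
tests are made about the profile of the cohort *mean* occupancy, which
is unbiased under the null, rather than about the mean of per-larva
profiles.

Species are summarised by `tp_opt()` (the window with the maximal mean
preference; ties resolve to the coolest window) and `tp_breadth()`:
per-window exact sign tests of median zero on the nonzero preference
values, Benjamini-Hochberg corrected across the 71 windows.
Significant-positive windows are "strong preference", significant
negative ones aversive, and the breadth is the contiguous non-aversive
run containing Tp_opt. BH is used because the multiple-testing method
is a free choice here; it is the least conservative standard option.
Between-species window-wise comparisons use Mann-Whitney U tests
(`compare_profiles_mwu()`), again BH-corrected, because preference
values are far from normal.

## Track processing

Raw tracker output is cleaned in the order the assay pipeline uses:

1. `filter_short()` removes tracks under 10 s (strict `<`, so a track
   of exactly 10.0 s is kept).
2. `join_clashes()` repairs larva collisions: when two tracks end on
   the same frame, each is joined to the reciprocally closest track
   starting afterwards, ranking candidates lexicographically by time
   gap then spatial gap. Only mutual nearest pairs join, and passes
   repeat until stable. A pass may select chains (X→Y and Y→Z); these
   are resolved to the earliest id, which is safe because a successor
   always starts after its predecessor ends (no cycles).
3. `join_fragments()` repairs tracking dropouts in three staged rounds
   — (150 px, 22.5 s, < 15 px/s), (500 px, 75 s, < 30 px/s), then
   unrestricted — each iterated to a fixed point with the same
   mutual-nearest rule.
4. `filter_nonmoving()` removes larvae that moved at most 0.5 mm
   cumulatively *and* at most 0.3 mm from their origin (both criteria
   required, reading the rule literally as a conjunction).
5. `remove_burnin()` drops the first two minutes.
6. `assign_temperature()` attaches to every sample the value of the
   thermal frame nearest in time (ties to the earlier frame) at the
   pixel nearest the *head* — larval thermosensors sit at the head tip
   — with centroid lookup available as an option. Out-of-grid positions
   clamp to the edge pixel and are flagged.

Internally everything is millimetres and seconds; pixel thresholds are
converted once through the camera scale (default 4 px/mm — the study
never states its scale, so the default is a round, plausible value and
is explicit in every signature that needs it). The 10 s filter is not
re-applied after joining.

## Thermal QC

`smooth_spikes()` replaces any pixel differing from both temporal
neighbours by more than 3 °C with their mean (ends use the single
neighbour). The pass repeats to a fixed point so the operation is
idempotent; isolated single-frame spikes — the failure mode of the
thermal camera used — are corrected in one pass. The 3 °C threshold
reuses the QC fluctuation bound since no separate value is stated.
`qc_gradient()` then requires, over the run: ≥ 5% of pixels below
17.5 °C in more than 90% of frames; likewise above 24.5 °C; and no
pixel spanning more than 3 °C between its extremes. The fluctuation
rule is applied after smoothing (the ordering is unstated in the source
protocol; applying it before would conflate camera artefacts with
gradient instability).

## Navigation metrics

`windowed_velocity()` uses a centred 3 s window stepped one frame at a
time (path length / window duration); edge windows are truncated and
flagged `partial`. Body-length normalisation divides by twice the
median head-to-centroid distance. `windowed_tortuosity()` computes
`1 − net displacement / accumulated path` per window size
(2, 5, 10, 20, 30 s) and averages the sizes available at each frame;
zero-path windows are undefined and excluded. `detect_head_sweeps()`
flags body-bend excursions above 30° that return below 10°, merges
peaks closer than 2 s (keeping the larger) and accepts sweeps above
45°; the bend magnitude is used because the tracker's sign convention
(left/right) is irrelevant to sweep size. Zone contrasts
(`zone_differences()`) resample metric values 1000 times per contrast
between the cool/mid/warm equal thirds of 17-25 °C
(boundaries 19.67 and 22.33 °C); trends across temperature are ordinary
least squares per group. A windowed metric belongs to the zone of its
central frame's assigned temperature.

## The cross-inhibition agent model

Larvae sense temperature with antagonistic cooling- and warming-cell
circuits that cross-inhibit. The model keeps this balance explicit and
linear: circuit weights

$$w_{cool} = 0.5 + s\,(T - T_{hsp}), \qquad
  w_{warm} = 0.5 + s\,(T_{hsp} - T),$$

clamped to [0, 1], overlap at 0.5 exactly at the homeostatic set point
$T_{hsp}$; their difference is the gain
$G(T) = w_{warm} - w_{cool} = 2s\,(T_{hsp} - T)$. A Weber-Fechner
perception signal integrates relative temperature change with decay
$c_O = 1$:

$$\dot A_O = -c_O A_O + G(T)\,\frac{\dot T}{T},$$

discretized by forward Euler at $dt = 0.1$ s (matching the 10 Hz
tracking), with $T$ in °C as the model is printed. Locomotion is a
constant-speed run-and-turn walk with reflective walls; the turning
probability per step is

$$p = \mathrm{clip}\big(dt\, r_0\, (1 - k\, A_O),\ 0,\ 1\big),$$

so negative $A_O$ (aversive context: e.g. warming above the set point)
raises turning and positive $A_O$ suppresses it — classical
klinokinesis. $s = 0$ gives a temperature-blind agent: zero gain,
unbiased walk.

Three locomotor constants are package choices, all exposed in
`agent_model()`:

* `speed_mm_s = 0.8` — a typical third-instar crawl speed;
* `base_turn_rate_hz = 0.3`, `turn_sigma_deg = 60` — a persistence
  length of a few millimetres, diffusive at arena scale;
* `turn_gain = 20000` — the coupling from perception to turning. On
  this arena the steady-state $|A_O|$ is of order $10^{-5}$–$10^{-3}$
  over the slope grids explored (gradients ≈ 0.4 °C/mm at most, speeds
  < 1 mm/s, division by $T \approx 21$), so an order-one coupling
  would leave turning essentially unmodulated and every slope would be
  behaviourally blind. The default was calibrated once so that the
  turning-rate modulation spans roughly 10–80% across the slope grid,
  giving cohorts whose occupancy visibly concentrates near $T_{hsp}$
  and separates set points two grid steps apart; it was then frozen.

The thermoscape (`thermoscape_config()`) is the plate baseline (21 °C)
plus peak-normalised Gaussian bumps at the four source positions (two
at 14 °C on one diagonal, two at 28 °C; spread 0.1 in normalised arena
units). Peak normalisation — the field equals the source temperature at
the source centre — is forced by pinning both the plate and the source
temperatures; an unnormalised density could not reach 14 °C at a cold
source.

The cohort stepper is compiled (Rcpp) for throughput but draws from R's
RNG in a fixed per-agent order, so a pure-R reference stepper
(`step_agents()`) reproduces its trajectories exactly under the same
seed; the test suite asserts that equality.

## ABC rejection-sampling fits

`fit_grid()` simulates a cohort at every (set point, slope) cell —
default grids: set points 17-25 °C in 0.5° steps; slopes
0.0005-0.007 in 0.0005 steps, with the coarse first-round grid
0.0025-0.05 also available — scores each agent's preference profile
against a 2000-agent temperature-blind null, and accepts an agent when
the Euclidean distance between its 71-window profile and the target
(empirical species mean) profile is at most 1.75. The distance is over
the full 71-window vector; the grid output records the profile length
so the threshold can be rescaled by $\sqrt{m/71}$ for other grids. The
best fit is the maximal-acceptance cell (ties towards the smaller
slope, then the cooler set point); the 95% credible region is the
smallest set of highest-acceptance cells holding 95% of the total
acceptance mass (an HPD-style reading of "the 95th percentile of the
2D distribution"), which by construction always contains the best-fit
cell. Per-cell seeds derive from the master seed plus the cell index,
so results are independent of evaluation order.

`predictive_check()` simulates a cohort at the fitted parameters,
takes each agent's own Tp_opt, and tests the empirical Tp_opt against
them with the permutation scheme of the source analysis: the statistic
is $D = |obs - \overline{sim}|$, the observed value is pooled with the
simulated ones, a random pool element is designated "observed" per
permutation, and the p-value is the add-one-corrected fraction of
permuted statistics at least as large as $D$ (strictly positive by
construction; its floor is ≈ 1/(n+1) where n is the pool size).

## Phylogenetic post-processing

`bm_ancestral_states()` estimates each internal node's trait value as
the GLS root state of the tree re-rooted at that node, with the tip
covariance built from patristic distances
($C_{ij} = (d_{ri} + d_{rj} - d_{ij})/2$) — the maximum-likelihood
estimate under Brownian motion. Estimates are equivariant under origin
shifts of the trait. `lineage_shifts()` reports tip value minus parent
estimate — the quantity the comparative analysis actually interprets —
rather than a model-based shift regression, which is out of scope
here. `phylo_anova()` computes the ordinary one-way F statistic and
calibrates it against traits simulated under Brownian motion on the
tree, with the rate estimated by REML (ML by flag); the p-value uses
the add-one estimator. Degenerate inputs are defined: identical trait
values give p = 1; perfect group separation gives an infinite F that
is beaten only by infinite simulated F values.

## Synthetic-data generator: what it does and does not emulate

The generator reproduces the *structure* of the assay data: 10 Hz
FIMtrack-style tables (px coordinates, head position, body-bend angle),
thermal frames every 20 s with Gaussian pixel noise and single-pixel
+8-15 °C spikes, track fragmentation (2-10 s dropouts), clash events
(two tracks ending on one frame, restarting under new ids one frame
later, the trigger the clash joiner keys on), and non-movers that
twitch below both movement thresholds. Locomotion comes from the same
agent model the fits assume. It does *not* emulate: body posture and
peristalsis (the synthetic bend angle is the heading change, so
absolute sweep sizes are not comparable to real larvae), velocity
modulation with temperature (agents crawl at constant speed; real
larvae slow down in preferred zones — a stated limitation of the model
family), tracker identity swaps without track breaks, or optical
artefacts. Passing tests therefore demonstrate correct bookkeeping and
internally consistent inference — e.g. that generating parameters are
recovered by the ABC fit — not that the model captures every feature
of real larval behaviour.

## Numerical choices and degenerate inputs

* Windows are exact unions of ten 0.1 °C fine bins, so window
  occupancy is a rolling sum with no edge ambiguity; fine bins span
  14-28 °C (the thermoscape's range) and clamp outside.
* Nearest-in-time frame lookup breaks ties towards the earlier frame;
  nearest-pixel lookup rounds half up, clamping and flagging positions
  off the grid.
* `tp_profile()` defines 0/0 as 0; `windowed_tortuosity()` excludes
  zero-path windows from the window-size mean.
* Joining tie-breaks: lexicographic (Δt, Δd), then the smaller track
  id; filters are order-independent.
* Empty inputs return empty outputs (not errors) wherever a run could
  legitimately produce none: zero larvae, tracks entirely inside the
  burn-in, empty track tables.
* The simulated problem sizes in the tests and the analysis scripts
  (hundreds of agents per cohort, 60-100 agents per ABC cell, reduced
  slope grids) are chosen so the full suite completes in minutes on
  one core; all scale linearly if increased.

## Known limitations

The locomotor model is the minimal turning-rate modulation consistent
with the cross-inhibition circuit; it omits speed modulation, head-cast
kinematics and body mechanics. The Weber-Fechner division by
temperature in °C follows the model as printed — with Kelvin the
perception signal would be ~14x smaller and the calibrated `turn_gain`
correspondingly larger, with no qualitative change. Slope and set point
are fitted assuming symmetric, linear circuit weights; asymmetric or
nonlinear weightings are out of scope. The sign-test breadth pools
larvae across runs and strains; hierarchical strain effects are not
modelled.
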