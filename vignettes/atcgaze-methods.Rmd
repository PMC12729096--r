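---
title: "Methods: gaze-based workload and conflict-resolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-based workload and conflict-resolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atcgaze)
```

This vignette documents the models behind `atcgaze`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## Geometry

All screen coordinates are centimetres with origin at the display's
top-left corner, y downward; this is the frame in which the AOI geometry
is defined. Visual angle follows the frontal subtense formula
$\theta = 2\arctan\!\big(e/(2d)\big)$ for an extent $e$ at distance $d$;
its inverse, $e = 2d\tan(\theta/2)$, turns the 1° fixation dispersion
bound into screen units (1.047 cm at 60 cm). The default geometry is a
61 × 34 cm display viewed at 60 cm and sampled at 30 Hz; viewing distances
outside 30–120 cm trigger a warning rather than an error, since remote
trackers tolerate a band of head positions (50–80 cm is typical).

## Event detection

**Blinks** are maximal runs of samples in which *both* eyes are invalid,
with run duration defined as (number of invalid samples) × sample period.
Runs whose duration falls in the closed band [100, 600] ms are blinks;
longer runs are track loss, shorter runs are treated the same way
(sub-100 ms flicker is indistinguishable from tracker noise at 30 Hz and
is never counted as a blink). The band edges are inclusive because the
definition is a closed interval with no stated edge rule. One-eye-invalid
samples never contribute to blink runs — a blink is a *simultaneous* loss
— but they retain the valid eye's position and pupil reading.

**Fixations** use a dispersion-threshold (I-DT) procedure. The dispersion
metric is the maximum pairwise Euclidean distance among the window's
samples — a containment bound, read literally from the definition of a
fixation as gaze staying within 1° — not the sum-of-ranges variant; windows grow over consecutive position-valid
samples while the bound holds, and a window is emitted as a fixation when
growth stops if its duration (n samples × period) reaches 100 ms,
scanning then resuming after the window. When a too-short window stops
growing, the start advances one sample — this makes the detector exactly
equal to a left-to-right exhaustive search over maximal windows, which is
how the test-suite oracle is implemented (full pairwise distances computed
from scratch per window). A single position-invalid sample terminates the
current window; we deliberately do not interpolate across dropouts, since
at 30 Hz each interpolated sample fabricates 33 ms of data. The hot loop
is implemented in C++ (incremental membership test: a new sample joins the
window only if it is within the bound of every current member).

Durations use the convention `end_ms = last sample time + period`
(exclusive end), so a 12-sample window has duration 400 ms and events
tile the timeline without gaps at sample boundaries.

**Pupil**: per-sample diameter is the mean of the available eyes (one eye
suffices); the session index is the mean over all such samples. Sessions
with no valid pupil sample yield `NA` with a warning. Zero-blink sessions
have an undefined mean blink duration, which propagates as missing and is
excluded listwise from that metric's ANOVA.

## Areas of interest

The three static AOIs tile the display: the active sector is the centred
27.5 × 20.5 cm rectangle (25.81° × 19.39° at 60 cm), the flight-plan
sheet is 17 × 7.5 cm flush to the top-right corner, and out-of-sector is
the complement. The sheet and sector rectangles share a thin boundary
strip; assignment precedence (sheet > sector > complement) makes the
effective regions pairwise disjoint, so AOI fixation times conserve
exactly: sector + out-of-sector + sheet = total on-display time.
Rectangles are closed on their left/top edges and open on right/bottom,
giving deterministic boundary behaviour. Whether the out-of-sector region
includes the sheet area was an open call; we keep the three regions
disjoint.

Dynamic AOIs are equal-sized rectangles (default 3 × 2 cm including the
data tag; the size is configurable since only their equality is fixed)
centred on each aircraft's projected position and tracked automatically
from the trajectory — the moving-target equivalent of hand-adjusting the
frames. A fixation is assigned to the aircraft whose AOI contains its
centroid for the greatest fraction of the fixation's duration on the
sample grid; ties break to the nearest AOI centre at the fixation
midpoint; never-contained fixations are unassigned. Sliding-window
attention shares use a trailing 10 s window stepped at one sample period
(the finest grid, since nothing coarser is canonical).

Cumulative fixation time on a conflict aircraft is accumulated over a
per-conflict analysis window, clipped at the aircraft's sector-entry time
(first grid time its symbol is inside the sector rectangle) for aircraft
entering after the window starts. The windows — [0, 180] s for the Easy
conflict and [0, 300] s for the Difficult one — are the package's own
choice: they span each conflict's build-up through shortly after its
scripted violation, matching the span over which conflict attention is
meaningfully defined.

## Separation checking and interventions

Separation is lateral horizontal Euclidean distance (NM) and absolute
altitude difference (ft). A loss of separation requires both to be
*strictly* below the minima (5 NM, 1,000 ft) simultaneously — "at least"
the minima is safe, so a pair exactly at 1,000 ft is separated. The
checker scans a 1 s grid (scripted times are whole seconds; the grid is
configurable) over all requested aircraft pairs with the intervention log
applied, returning the earliest violating grid time. Altitude clearances
take effect at their issue time with a 1,500 ft/min climb/descent ramp
rather than instantaneously — instantaneous level changes would trivialise
resolution timing. Speed clearances rescale progress along the route from
the issue time. Two altitude clearances on one flight overlapping in time
(the second issued before the first's ramp completes) are rejected as
contradictory. A conflict is *solved* when its aircraft are never in
violation over the whole scenario.

## Statistics

The 2 × 3 repeated-measures ANOVA is computed from the standard
multivariate within-subject decomposition (via `car::Anova` on an
intercept-only multivariate fit); partial η² is SS_effect / (SS_effect +
SS_error). Sphericity is assessed with Mauchly's test for effects with
more than two levels, and the Huynh-Feldt df correction is applied when
Mauchly's p < 0.05 (a sphericity-violation trigger needs a test level, and
0.05 is our choice). Degenerate tables (zero within-subject
variance) report F = 0 rather than 0/0. Bonferroni pairwise comparisons
are paired t-tests with p multiplied by the comparison count, capped at 1.
Spearman correlations between the workload and ocular indices are computed
over the **six condition means** (not participant-level values), with
exact p-values and Fisher-z intervals.

Solver/non-solver comparisons use Mann–Whitney U (exact for small untied
groups, normal approximation with tie correction otherwise — the
`wilcox.test` convention, verified against exhaustive permutation for all
group sizes ≤ 8). The forward-stepwise binomial logistic regression enters
the candidate with the smallest score-test p ≤ 0.05, removes entered
predictors whose Wald p ≥ 0.10 after each entry, and caps at 25
iterations — the common defaults of the classic stepwise implementations,
which the procedure description leaves open. Reported per step are the
likelihood-ratio χ² of the entry and the score p; the final model carries
McFadden's R² = 1 − lnL/lnL₀ and VIFs (1/(1−R²ⱼ) from cross-predictor
regressions; exactly 1 for a single predictor). Quasi-complete separation
is flagged and the coefficients marked unreliable rather than suppressed.

## The synthetic cohort

The generator emulates the study conditions end to end: 24 participants ×
6 counterbalanced conditions, 16-min (960 s) sessions at 30 Hz.

**Scenarios.** The world is a linear viewport: the sector's 60 NM
east-west extent maps isotropically onto the 27.5 cm sector rectangle.
The 12-aircraft high-complexity scenario embeds the two scripted
conflicts. The scheduler places converging pairs so both aircraft reach
the crossing point simultaneously; with relative speed $w$, lateral
separation is $(T_c - t)\,w$, so placing $T_c$ = (target − ½ grid) + 5/w
makes the first violating grid time exactly the target, and the climbing
aircraft's initial altitude is set so the vertical minimum is crossed 30 s
earlier. The Easy pair (level POB456, 450 kn; climbing non-standard
HYG532, 430 kn, 60° crossing, levelling at 35,000 ft) violates at 140 s;
the Difficult trio (level KET456 at 33,000 ft; climbing non-standard
REV756; converging GPL751 at 37,000 ft, 2,000 ft above, involved but never
violating) violates at 240 s; SRT346 flies a look-alike climbing route
without conflict. Every scheduled geometry is verified by forward
simulation through the separation checker at build time. All background
aircraft fly mutually safe flight levels (≥ 1,000 ft apart), so no
unscripted loss of separation is geometrically possible — verified
exhaustively in the tests. Unresolved scripted pairs pass through zero
lateral distance at co-arrival; only the violation time, not the miss
distance, is scripted.

**Gaze.** An alternating fixation/transit renewal process: gamma fixation
durations (mean 300 ms, shape 4, floor 4 samples), 1–2 valid transit
samples between targets (so transits can never masquerade as blinks),
target categories {conflict aircraft, other in-sector aircraft, sector
background, out-of-sector, sheet} with condition-dependent weights. The
static attention split targets 78/83/88% sector share for low/medium/high
complexity and 5%/3% sheet share for 6/12 aircraft (bracketing the
observed ≈83/13/4% split); ordinary traffic is fixated only while inside
the sector, conflict aircraft anywhere on screen, with the expected
pre-entry monitoring time deducted from the free out-of-sector budget.
Conflict gaze budgets are calibrated so expected cumulative fixation time
over each conflict window matches the solver/non-solver targets (35.67 vs
16.11 s Easy; 68.56 vs 81.50 s Difficult — note the Difficult direction
reverses: non-solvers stare longer yet fail), via
weight = target / (duty × effective window length), where duty is the
predicted fixation duty cycle net of transits and blinks and the effective
length nets out pre-entry clipping. Blinks are Poisson arrivals (rates
13–11.5/min at low traffic, 9.5–8.3/min at high, decreasing with
complexity; participant-level lognormal rate multipliers) with
truncated-normal durations (means 315/295 ms low/high traffic, SD 60,
kept strictly inside the detection band), injected as both-eye-invalid
gaps with ≥1.5 s spacing so ground truth is unambiguous. Pupil diameter is
the condition baseline (3.41/3.44 mm low/high traffic; between-participant
SD 0.32 mm) plus AR(1) noise (φ = 0.97, stationary SD 0.08 mm) and a
0.03 mm session-level jitter; 1% of samples lose one eye at random.

**Behaviour.** Solver status is Bernoulli per participant (8/24 Easy,
13/24 Difficult — the tabulated group sizes). Easy solvers issue one
altitude clearance on HYG532 (to 32,000 ft, at 60–110 s, early enough
that the descent restores separation before closure); Difficult solvers
stop REV756's climb at 30,000 ft (140–200 s) plus at least one further
intervention. Non-solver logs are empty or contain only post-violation
actions, which cannot change the outcome since the first violation has
already occurred. Acceptance actions for the sector-entering flights are
always logged ≈12 s after entry. ISA and NASA-TLX are monotone noisy
functions of condition demand with participant offsets, rounded and
clamped to their scales.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: pupil light reflex and luminance coupling,
fatigue drift over the 3 h session, head movement and calibration decay,
saccade kinematics (transits are linear interpolation), smooth pursuit,
scanpath strategy structure (circular/linear scanning), and any coupling
between workload and fixation duration. Effect recovery on this generator
demonstrates that the measurement chain is faithful, not that the
physiological effects themselves are real.

## Problem sizes and reproducibility

All randomness flows from one integer seed; per-session substreams are
derived by fixed offsets, so any session can be regenerated in isolation
and full runs are bit-reproducible (the pipeline writes a config hash
into every output). The test suite exercises the effect-sign pattern on
20 full-scale cohorts (24 × 6 × 960 s), the ANOVA type-I error on 200
reduced null cohorts (8 participants, 60 s recordings — the metric
distributions, not the scenario scripting, are what the null calibration
needs), the I-DT oracle on 100 random 500-sample streams, and blink
recovery on 100 streams with known injected gaps. These sizes are the
package's calibration choices for a thorough but routine local run.

## Known limitations

- Complexity manipulations affect the generator's attention, blink and
  subjective-score parameters, not the scenario route structure itself;
  scenario files differ across complexity only in their label and the
  scripted conflicts.
- The linear viewport has no pan/zoom and no data-tag occlusion handling;
  dynamic AOIs never overlap in the packaged scenarios, so the
  assignment tie-break is rarely exercised by simulation (it is tested
  directly with constructed fixtures).
- Speed clearances model proportional ground-speed change along the
  filed route; heading changes (vectoring) are not implemented, matching
  the intervention vocabulary analysed (altitude/speed).
- At 30 Hz, blink durations are quantised to 33.3 ms; recovered durations
  are therefore exact only up to one sample period.
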