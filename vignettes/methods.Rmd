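---
title: "Models and methods behind roboshoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind roboshoal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`roboshoal` is a virtual laboratory for a robot-demonstrator door-choice
learning experiment in zebrafish.  A subject swims in the focal compartment
of a 74 x 30 cm tank; one of two doors in a transparent partition opens
when the subject stations in an unmarked 6 x 6 cm zone in front of it for
at least 3 s out of any trailing 5 s, giving access toward a shoal of
conspecifics.  In the social condition a robotic replica demonstrates the
correct door during a 10 min confinement phase before each of 20 training
trials; learning is probed in doors-closed test sessions before training
and after trials 10 and 20.  The package implements the computational
chain of such an experiment — swimming simulation, demonstration
scheduling, video tracking, closed-loop triggering, behavioral metrics,
and mixed-model statistics — so that every stage can be validated
end-to-end on synthetic data with known ground truth.

## The burst-and-coast locomotion model

Zebrafish swim with sudden tail beats followed by longer coasting phases.
The simulator (`simulate_trajectory()`) is a stochastic walker with state
(position, heading, speed) on a 20 Hz grid:

* **Bursts** arrive as a Poisson process with rate `burst_rate`
  (default 1 /s).  At a burst, speed resets to a draw from
  N(`burst_speed_mean` = 10, `burst_speed_sd` = 3) cm/s (clipped at 0) and
  the heading receives a Gaussian increment with SD `turn_sd` = 0.6 rad.
* **Coasting**: between bursts speed decays exponentially with time
  constant `coast_decay_time` = 0.4 s, so log-speed falls linearly with
  slope −1/τ (a property the tests assert exactly).
* **Attraction**: the mean of the burst heading increment is the wrapped
  bearing error toward an attraction point scaled by
  `attraction_gain` ∈ [0, 1]; a gain of 0 gives an unbiased walker, a gain
  of 1 re-orients fully toward the target on average.
* **Walls** reflect the fish specularly; within 3 cm of a wall a small
  extra heading jitter (SD 0.3 rad) prevents boundary sticking.

The source experiment generated replica trajectories from a zebrafish
locomotion model published separately, whose parameter values are not part
of this package's inputs.  The walker here is therefore a deliberately
generic burst-and-coast stand-in with the qualitative structure above.
Its defaults were chosen once to give realistic speeds of roughly
1–3 body lengths per second and are all configurable; no empirical claim
rests on their exact values.

## The synthetic cohort and what it does (not) emulate

`cohort_design()` reproduces the study design: 36 subjects, 18 per
condition, two batches of nine per condition, correct door fully
counterbalanced across conditions, batches, and subjects, sex ratio 5:4
per batch, 20 training trials plus tests at 0/10/20 completed trials.
Three effects can be injected:

* **Learning** — attraction gain toward the correct door grows linearly,
  `min(1, pref_drift × trial)`.  Default `pref_drift = 0.02` (gain 0.4
  after 20 trials), a magnitude at which preference rises visibly above
  0.5 but stays far from ceiling.  Linear growth is the simplest drift
  that lets the statistics stage demonstrate effect recovery; it is a
  modelling convenience, not a learning theory.
* **Social boost** — additional per-trial gain in the social condition.
  The default is 0 because the experiment this package models found no
  individual-vs-social difference; a nonzero value exercises the
  Condition terms of the analysis.
* **Side bias** — a constant lateral attraction toward one side wall
  (default gain 0.1), emulating the uncontrolled environmental bias that
  the analysis encodes as the correct-door-location factor.

Test sessions are simulated with doors closed and the gain implied by the
number of completed trials.  Training releases last 30 min (trials are
right-censored at that limit); test releases last 10 min, following the
protocol's 10 min observation period for tests.

The generator emulates occupancy statistics, not fish biomechanics: there
is no body undulation, hydrodynamics, or 3D motion, no inter-individual
variability in swimming parameters beyond the injected effects, and
learning is imposed, not emergent.  A green statistical test therefore
establishes that the analysis recovers effects of the stated form at the
stated size from trajectories with realistic occupancy structure — not
that real fish behave like the walker.

## Rendering and tracking

`render_frames()` draws each fish as a dark ellipse (major axis one body
length) on a white background at a configurable resolution (default
640 x 480, the tracking camera's resolution).  The tracker
(`track_video()`) mirrors the live system: consecutive frames are
differenced, thresholded, morphologically closed, hole-filled, and
connected components above an area floor become centroid detections; a
constant-velocity Kalman filter per identity fills detection gaps
(flagged `interpolated`, held and invalidated beyond a 1 s horizon), and
the commanded replica position disambiguates replica from subject.

Frame differencing only sees change.  A live fish undulates continuously,
so its outline moves every frame; a rigidly rendered ellipse does not, and
a coasting fish would vanish from the difference image.  The renderer's
`wobble_amp` option emulates undulation by alternately dilating and
contracting the silhouette each frame (sides more than ends, like a tail
sweep), which turns the difference image into a closed ring around the
fish that hole-filling restores to a solid, centred blob.  Fixtures for
tracker validation enable it; with it, tracking RMSE on clean fixtures is
about 0.2 cm (contract: < 0.5 cm).  Two residual artifacts are inherent to
the approach and documented rather than hidden: a detection marks the
union of two consecutive silhouettes, so its centroid can sit anywhere
between the paired positions; and when the walker's centre touches a wall
the silhouette is clipped and the centroid biases inward by up to ~1 cm —
a point-mass artifact a real fish body would not produce.

## The trigger rule and censoring

`evaluate_trigger()` implements "at least 3 s of any 5 s" as a trailing
window evaluated at every 20 Hz sample: the door opens at the first sample
where the count of presence samples in the last 100 (clipped to the
elapsed series at the start) reaches 60.  Sample i covers the interval
((i−1)Δt, iΔt], so 60 consecutive presence samples from release trigger at
exactly 3.0 s, and no trial can ever record T < 3 s.  The start-up clip
means continuous presence can trigger before 5 s have elapsed; the
original system's start-up behaviour is unspecified, and the trailing
(sliding) window is the strictest reading of "any 5 s".  Trials that never
trigger within 30 min are right-censored with T = 1800 s, exactly as the
source analysis entered them.

## Behavioral and learning measures

All measures are computed per trial on the release phase up to door
opening (or the full limit when censored), with interpolated samples
excluded from displacement-based quantities but retained for occupancy:

* door-proximity times τ_C, τ_I over the two trigger zones and the
  preference index PI = τ_C/(τ_C + τ_I), undefined (never zero) when the
  subject visited neither zone;
* wall times T₁–T₄ within 3 cm of the four focal-compartment walls and
  the reward index RI = T₁/ΣTᵢ, where wall 1 is the door partition — the
  wall nearest the conspecifics, which is what RI is meant to quantify
  (the source defines the index but not the wall numbering; this choice
  is recorded as a package decision);
* trajectory entropy H = −Σ Pᵢ log₂ Pᵢ over a 10 × 10 occupancy grid on
  the focal compartment (the formula's 100-bin summation limit; the grid
  is configurable), with 0·log 0 ≡ 0, so H ∈ [0, log₂ 100];
* heading error θ_C: the absolute angle between the displacement heading
  and the bearing to the correct door's centre, in degrees; samples
  slower than 0.5 cm/s are excluded to avoid arccos of near-zero vectors;
* speed, acceleration, and turn rate as the literal finite differences
  ‖x_{t+1}−x_t‖/Δt, ‖v_{t+1}−v_t‖/Δt, and cos⁻¹(v̂_{t+1}·v̂_t)/Δt.  The
  acceleration is read as the magnitude of the velocity difference (the
  typeset formula is ambiguous between that and the difference of
  magnitudes; the vector reading is implemented);
* freezing time F: Δt times the number of samples whose centred 2 s
  window (edge-clipped) has net endpoint displacement below 4 cm — the
  strictest literal reading of "moved < 4 cm"; a path-length variant is
  available behind `metric_options(freezing_mode = "path")`;
* avoidance A: whether the distance to the correct door's centre exceeded
  2 body lengths (6 cm) within 15 s after opening; undefined on censored
  trials;
* modified preference PI_m: fraction of time in the middle of three
  equal-area bands along the tank width, where the replica stations.

Every measure has a naive per-sample loop oracle in the test suite that
the vectorized implementation must match exactly on random trajectories,
plus a reflection invariance property (mirroring the arena across its
mid-width line while relabeling doors leaves all measures unchanged).

## Statistics

`fit_lmm_type2()` fits linear mixed models (REML, `lme4`) with a random
intercept per subject and produces type II Wald chi-square tables in the
χ²/Df/p layout: each term is tested, respecting marginality, in the model
containing that term and every term not containing it; unordered factors
use sum-to-zero contrasts and the ordered test factor polynomial
contrasts, without which type II tests are not meaningful.  Interactions
non-significant in the full-model table (p ≥ 0.05, a threshold the source
does not state; both tables are always reported) are discarded from
highest order down, never removing a term contained in a retained one.
Singular fits set a flag on the table instead of failing.

`summarize_study()` mirrors the published analysis layout: PI and θ_C on
test data (condition × door location × test), T, PI, and θ_C on training
data (condition × trial × door location), a single conservative corrected
alpha of 0.050/3 ≃ 0.017 applied to all tables, and a Brown–Forsythe
Levene test (one-way ANOVA on absolute deviations from group medians) of
PI variability across the 12 condition × location × test groups.
Censored T values enter as recorded (1800 s), as in the source analysis —
a documented limitation, not a survival model.

Calibration is checked by simulation: on 500 reduced-size null cohorts
the empirical type I error of the trial term at α = 0.017 must fall
inside the exact binomial 95% interval, and on drift cohorts the
estimated trial effect must be sign-correct in ≥ 95% of replicates and
significant in a majority.  The reduced world keeps the study's 36
subjects and scales down trials (12) and release duration (90 s): the
per-trial PI is strongly bimodal (trials truncated at door opening often
yield PI exactly 0 or 1), so the Wald chi-square reference is only
trustworthy in the large-sample regime the real study occupies — at a
quarter of the rows (12 subjects × 8 trials) the same simulation shows
visible small-sample inflation (~0.03 at nominal 0.017).  That is a
property of Wald tests on such data worth knowing when using this
procedure on small pilot cohorts.

## Numerical and design choices

* Coordinate frame: origin at the focal-compartment corner, x toward the
  stimulus shoal, y across the width; cm and seconds throughout.
* Zone membership is boundary-inclusive, so samples exactly on grid lines
  are never dropped; the sample at exactly t = T is included in the
  scored window.
* Per-session seeds are derived from the master seed by a fixed integer
  recurrence, keeping every derived seed below 2³¹; the whole pipeline is
  a pure function of its configuration.
* The replica schedule absorbs slack into the final station segment so
  the demonstration phase is exactly 600 s; transits shorter than one
  20 Hz tick are realized as position holds.  The replica's transit speed
  (10 cm/s) and the waypoint coordinates are geometric conventions — the
  source shows them only schematically — and an infeasibility error is
  raised if 6 cycles cannot fit in 10 min at the configured speed.
* `run_virtual_experiment()` streams trials (simulate → session → score →
  discard), so the full-scale 828-session study runs in modest memory;
  ground-truth mode is the default and tracked mode exists to validate
  the vision stage on smaller cohorts.

## Known limitations

The walker's parameters are stand-ins, not fitted to the source data; the
renderer draws rigid (pulsating) ellipses, not undulating bodies; the
tracker is validated on two targets at most; censored trigger times are
analyzed as recorded values; and the package makes no claim about the
biology of observational learning — it reproduces the measurement and
analysis machinery, with synthetic ground truth as the only authority a
test can appeal to.
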