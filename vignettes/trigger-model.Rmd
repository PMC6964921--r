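---
title: "A predicted-error trigger model for catch-up saccades during smooth pursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A predicted-error trigger model for catch-up saccades during smooth pursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchup)
```

## The problem

During smooth pursuit of a moving target the eye accumulates position
error (PE, target minus eye, in degrees) and retinal slip (RS, target
velocity minus eye velocity, in deg/s). The oculomotor system must decide
when to interrupt pursuit with a discrete catch-up saccade: saccading too
eagerly costs vision through saccadic suppression, waiting too long
tolerates a blurred, eccentric target. `catchup` implements a stochastic
account of that decision and everything needed to study it end to end:
the double step-ramp task that probes it, a closed-loop simulation of a
tracking observer, a ground-truthed synthetic eye-trace generator, the
per-trial signal-processing chain, and the group statistics.

## The task

A trial starts with fixation 20 degrees left or right of center. A first
step-ramp (step of 2, 4 or 6 degrees away from center; ramp of 10, 20 or
30 deg/s back toward center) establishes steady-state pursuit. After a
uniform 500-700 ms, a second step-ramp perturbs the target: a position
step `ps2` within plus or minus 20 degrees and a velocity step `vs2`
uniform on [-50, 50] deg/s. The velocity step is expressed relative to
the ongoing ramp -- it is the change that creates retinal slip in a
tracking eye -- so the post-step target velocity is `vs1 + vs2`. The
position step is constrained so the target would re-cross the
extrapolated pre-step trajectory within a second
(`|ps2 / vs2| <= 1 s`), and the pair is resampled whenever the target
would leave the 30-degree half-screen during the 400-ms analysis window
(large steps are simply not shown). Two summary quantities follow
directly from the stimulus and the state of the eye:

* target-crossing time, `T_xt = -ps2 / vs2` (ms): when the stepped
  target re-crosses its pre-step trajectory; positive values are
  foveopetal (target returning), negative foveofugal;
* eye-crossing time, `T_xe = -PE / RS` (ms): when the eye's current
  trajectory would intercept the target. `T_xe` is reported as
  undefined when `|RS|` is near zero, where the ratio is unstable.

## The trigger model

The observer never sees PE and RS directly. Every millisecond it draws
noisy observations of the delayed retinal state (position noise SD 0.5
degrees for a clear target, 2.5 degrees for a blurred one; velocity
noise SD `1 + 0.2 |RS|` deg/s, i.e. signal-dependent noise, SDN) and
runs a Kalman filter on the two-dimensional state (PE, RS) with
constant-velocity dynamics: PE integrates RS, RS is a random walk.
Self-generated changes enter the filter as known control inputs -- an
efference copy of the eye's own movement -- so only target-generated
changes count as surprises; the filter covariance is inflated at each
perceived target step. Observations are suppressed while the (delayed)
retina was mid-saccade.

Because afference is delayed (60 ms here), the decision and motor stages
work on a forward-model extrapolation of the filter state to the current
instant using the known motor history. Without this compensation the
model re-triggers immediately after every saccade, because for one
sensory delay the estimates still describe the pre-saccadic world.

The decision variable is the predicted position error

\[ \mathrm{PE_{pred}}(t) = \mathrm{PE}(t) + dt \cdot \mathrm{RS}(t), \]

with horizon `dt = 150 ms` by default (90-290 ms is the plausible
range). Its variance combines the filter covariance propagated through
the extrapolation with a signal-dependent term
`(dt * sdn_coef * RS)^2`: uncertainty about where slip will carry the
target does not average away into the future. From the resulting
Gaussian belief the model computes the probability mass right of the
fovea, left of it, and inside it (foveal radius 2 degrees). The
accumulated quantity is the directional log probability ratio
`|log(p_right / p_left)|`, gated on the target being more likely outside
the fovea than inside; the extrafoveal-to-foveal log-ratio is available
as `conf_form = "foveal"`. The directional form was chosen because it is
the one with the right asymptotics: scaling signal and noise together
(which is what larger velocity steps do) leaves the rise rate bounded,
while precise small-noise estimates rise very fast -- so uncertainty
always slows the decision. Evidence accumulates at a rate proportional
to this confidence (negative increments floored at zero, a
rise-to-threshold), resets at each perceived target step and after each
executed saccade, and triggers a saccade at threshold (8, in
log-probability-ratio units). The threshold, foveal radius and delays
were calibrated once so that clear-condition median trigger times at
large `|PE_pred|` fall in the 150-200 ms band and the exclusion rate of
the analysis chain sits near the one fifth of trials typical of this
paradigm.

The executed saccade is planned from the delay-compensated estimate:
amplitude `PE + horizon * RS` with the horizon spanning the motor delay
(100 ms) plus half the saccade duration, duration from the linear main
sequence `2.2 ms/deg + 21 ms`, and a symmetric minimum-jerk profile.
Pursuit runs in parallel: eye acceleration follows the estimated slip
(rate constant 9 /s, so a large velocity step takes roughly 200 ms to
absorb -- slow enough that SDN is still alive when the decision is made)
plus a weak channel on the position error (0.3 /s), with a leak tuned to
a steady-state gain of 0.9.

## The synthetic-data generator

`generate_dataset()` produces labelled traces in two modes. Model mode
runs the closed-loop simulation above and logs every executed saccade.
Scripted mode synthesises a pursuit-only response (first-order velocity
dynamics, latency 100 ms, gain 0.9, time constant 40 ms, acceleration
saturated at 450 deg/s^2 -- pursuit cannot jump-start, and without the
cap its transient after a large velocity step would itself cross the
saccade detector's acceleration threshold) and injects minimum-jerk
saccades by a deterministic rule (trigger `180 + 600 / |PE_pred|` ms,
smooth below 2.5 degrees, optional jitter). The scripted rule is not a
scientific claim; it exists so the analysis chain can be validated
against exact ground truth. Blink faults (100-300 ms NaN gaps
overlapping the critical window) and dropout faults (isolated NaN
samples) exercise the exclusion rules at configurable rates.

The generator emulates the study conditions -- sampling rate 1000 Hz,
per-trial step-ramp statistics, clear/blurred alternation, 10 sessions
of 10 blocks of 50 trials per participant by default -- but not
eye-tracker artefacts (calibration drift, pupil-size coupling),
binocular disparities, or the heterogeneity of real observers, who vary
in pursuit skill and strategy. Passing tests therefore show the pipeline
and model are internally coherent and reproduce the qualitative
phenomenology; they are not a substitute for the deposited human data.

## The analysis chain

Per trial: eye position is low-pass filtered at 50 Hz with a
forward-backward Butterworth filter (order 2 per pass; NaN gaps split the
series into independently filtered runs, with odd-reflection padding at
the ends because an unpadded forward-backward pass assumes a zero
initial state). Velocity and acceleration come from central differences,
exact for quadratics. Saccades are spans where |acceleration| exceeds
750 deg/s^2, merged within 20 ms; onset and offset are refined to the
local minima of directed velocity on either side of the velocity peak,
then nudged to the first rise above 5% of the peak-to-baseline
excursion (the raw threshold crossing sits about 10 ms down the filtered
flank of the movement). Saccade direction is judged against the local
pursuit baseline rather than net displacement, which misleads for small
saccades against fast pursuit.

Exclusions, in order: missing eye samples at or after the second step
within the critical window (blinks, dropouts); a saccade in flight at
the step; double saccades (inter-saccadic interval under 100 ms); and
saccades made to the first ramp's trajectory, identified by a landing
closer to the extrapolated pre-step trajectory than to the actual
target, or a direction opposite to the position error at onset.

Metrics per trial: trigger time (first post-step saccade onset minus
step time, within the 400-ms window); class (early < 175 ms, late
otherwise, smooth if no saccade in the window); `PE_pred` averaged over
the 50 ms after the step (for trigger-time analyses, with the raw PE and
RS window averages kept alongside); and the pre-saccadic sample 100 ms
before onset for saccade trials or the 400-ms window average for smooth
trials (for occurrence analyses). All bin edges downstream are half-open
`[lo, hi)`, and quartiles use linear interpolation -- stated explicitly
because IQR values depend on the convention.

## Group statistics

`summarize_bins()` gives per-subject, per-condition medians and IQRs of
trigger times and trial-type proportions under the canonical schemes
(PE_pred below -5 / [-5, 5) / 5 and above, and 2-degree fine bins; T_xt
negative / [0, 400) / 400 and above; 50-ms T_xe bins; 10-deg/s |VS|
bands plus the coarse 0-10 / 20-30 / 40-50 bands). `rm_anova()` wraps
`stats::aov` with an `Error(subject/...)` stratum, averages duplicate
cells, drops incomplete subjects listwise, and reports partial
eta-squared; cells need at least 5 trials to enter. Post-hocs are all
pairwise paired t tests with Bonferroni correction (p multiplied by the
number of comparisons, capped at 1). Bayes factors use the BIC
approximation `BF10 = exp((BIC_null - BIC_alt)/2)` with subject as a
blocking factor -- documented as an approximation under the
unit-information prior, not a replication of any particular Bayesian
ANOVA implementation.

The four directional checks evaluated by `hypothesis_checks()`:

1. small `|PE_pred|` at the step produces longer and more variable
   trigger times than large;
2. the foveopetal `[0, 400)` ms T_xt bin has the longest and most
   variable trigger times of the three;
3. target blur lengthens trigger times, most strongly at small
   `PE_pred`;
4. larger `|VS|` lengthens trigger times at matched T_xt and lowers the
   saccade proportion at matched `PE_pred` (the SDN signature). The
   occurrence half is deliberately evaluated at matched `PE_pred`: at
   matched T_xt the task geometry makes `|PE_pred|` itself proportional
   to `|VS|`, so the trigger signal grows as fast as the noise and no
   noise model can lower the saccade proportion there.

## Recovering the extrapolation horizon

`recover_extrapolation_horizon()` scans dt over 90-290 ms. The default
objective exploits the smooth zone: trials stay smooth exactly when
`PE_pred(dt)` hovers near zero, so the generating horizon is the dt at
which `|PE_pred(dt)|`, recomputed from the step-window PE and RS
samples, best separates saccade from smooth trials (minimum logistic
deviance). On model-mode data this lands within about 20 ms of the
generating 150 ms. The alternative trigger-time-variance objective is
kept for comparison; its minimum is broader and sits some 25 ms high,
because the accumulator integrates a growing predicted error and so
weights slip slightly beyond the extrapolation itself.

## Numerical choices and degenerate inputs

* Confidence is computed in log space (`pnorm(..., log.p = TRUE)`); the
  foveal mass falls back to the nearer-edge tail when the interval
  probability underflows, and the rise rate is capped at `1e5` so
  zero-variance estimates stay finite.
* `T_xe` and `T_xt` return NA rather than dividing by a vanishing
  velocity; NA values are dropped from T_xe schemes only.
* Identical-cell ANOVAs report F = 0, p = 1; identical post-hoc pairs
  report p = 1 after capping.
* Bins with no trials are omitted; bins with no saccade trials carry NA
  medians, never zeros.
* Every generator accepts a seed and regenerates bit-identically.

## Problem sizes

The bundled analysis scripts and the package's own qualitative checks
simulate 5 observers x 2 sessions x 4 blocks x 50 trials (2000 trials).
These sizes were chosen as the smallest at which the binned medians and
proportion curves are stable; the full study design (15 participants,
75,000 trials) is available by leaving the schedule at its defaults.

## Known limitations

* The model is one-dimensional and horizontal; no torsion, no vertical
  component, no 2-D extension of the foveal zone.
* Acceleration is not part of the sensory state; targets are piecewise
  constant-velocity.
* The filter's noise magnitudes, threshold and foveal radius are
  calibrated to qualitative behaviour, not fitted to data by likelihood.
* Scripted-mode pursuit is deliberately simple (first-order, saturated);
  it does not model anticipatory pursuit or gain adaptation.
* The Bayes factors are BIC approximations and will not match values
  from dedicated Bayesian ANOVA software.
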