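---
title: "Estimating stride length and velocity from a shoe-embedded IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stride length and velocity from a shoe-embedded IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridekit)
```

## The problem

A six-axis IMU in a running-shoe midsole measures specific force
(accelerometer, gravity included) and angular rate (gyroscope) in a sensor
frame with x lateral, y dorsoventral (back-to-front of the foot) and z
craniocaudal. From these signals we want, per stride (one initial ground
contact of a foot to its next), the stride length in metres and the mean
velocity in m/s. stridekit implements four estimators over a shared
segmentation, a synthetic ground-truth generator, and agreement statistics.
This vignette records the modelling assumptions, parameter choices and
numerical decisions.

## Stride segmentation

Initial ground contact (IC) produces a sharp transient in the dorsoventral
acceleration $a_y$. We amplify it with squared per-sample differences,
$H[n] = (a_y[n] - a_y[n-1])^2$, and accept a candidate where $H$ exceeds
1000 (m/s²)² — an empirical threshold defined at 200 Hz; at other rates the
difference is rescaled by $f_s/200$ so the threshold keeps its meaning. One
candidate is taken per contiguous supra-threshold run, placed at the sample
immediately *before* the run: at that sample the impact has not yet
corrupted $a_y$, which matters for the confirmation step. That step
integrates $a_y$ backwards from the candidate to the previous zero crossing
(the onset of late-swing deceleration) and requires the integral to fall
below −3 m/s; impacts without a preceding swing phase (taps, drops) are
rejected. Accepted contacts must be at least 0.25 s apart — roughly one
ground-contact time — and windows outside (0.2, 2.0) s are dropped.

Two conventions worth stating. First, indices are 1-based (the natural R
convention) and windows are half-open `[start, end)`, so the stride sample
count is `end - start` either way. Second, the candidate-before-the-run
placement keeps `a_y[nIC]` on the pre-impact side; placing it on the first
supra-threshold sample would hand the swing-phase check a large positive
impact sample and make the zero-crossing scan terminate immediately. Both
placements are within three samples of the physical contact.

## The four estimators

**Stride time.** Relative stride length (stride length per body height) is
a non-increasing step function of stride time, tabulated separately for
male (13 intervals) and female (9 intervals) runners; the table ships as a
plain CSV in `inst/extdata/` and is validated on load (partition of
$(0,\infty)$, monotonicity, printed values). Intervals follow the
`(lower, upper]` convention of the printed rows. The estimate is
$d = h \cdot d_{rel}(t_{stride})$, $v = d/t_{stride}$. Gender is required;
no imputation.

**Acceleration.** Channels are smoothed with a centred moving average
(default 0.05 s, shrinking at the edges), and the integration value
$\iota[n] = \frac{1}{L+1}\sum_{i=0}^{L}\sum_{d}|s_d[n-i]|$ is evaluated at
steps detected as smoothed dorsoventral peaks above 30 m/s² separated by
0.25 s. The window $L$ defaults to 0.30 s, a typical swing duration. The
absolute value inside the sum is essential: without it the oscillating
swing acceleration cancels and $\iota$ loses its correlation with speed. A
second-degree polynomial $v = A + B\iota + C\iota^2$ is fitted by ordinary
least squares during training and applied at each detected step; stride
length is $v \cdot t_{stride}$, the only construction consistent with
$v = d/t$. Negative predictions are clamped to zero with a warning.

**Trajectory.** Per stride: find midstance as the minimum of the windowed
gyroscopic energy $g_x^2+g_y^2+g_z^2$ (0.05 s moving average, ties to the
earliest sample) within 0.250 s of the IC — the average stance time at up
to 6 m/s; initialize orientation from the mean specific force over ±0.05 s
around midstance (quasi-static, so it points along gravity), as the
shortest-arc rotation onto world +z with yaw left at zero; integrate the
gyroscope with the quaternion exponential-map update, renormalizing every
step; rotate specific force to the world frame and subtract
(0, 0, 9.81 m/s²); integrate twice with the trapezoidal rule, subtracting
from the velocity the line through its first and last samples (the
zero-velocity update) so both midstance velocities are exactly zero — the
endpoints are assigned 0 directly rather than trusting floating-point
cancellation. Stride length is the L2-norm of the final position; yaw is
unobservable but irrelevant for a norm (verified by a sensor-yaw invariance
test). Strides are re-segmented midstance-to-midstance, so a session with
K contacts yields K−1 full strides. An extended-Kalman-filter variant is
deliberately out of scope; dedrifting performs comparably for mean stride
velocity and tolerates 200 Hz sampling.

**Deep learning.** The 6-channel stride window is zero-padded to 200
samples (strides longer than 1 s at 200 Hz are rejected as too slow for the
architecture) and fed to: conv(32 filters, length 30, valid, ReLU) →
maxpool(2) → conv(16, 15, valid, ReLU) → maxpool(2) → flatten →
dense(128, ReLU) → dropout(0.30) → dense(1, linear). Feature lengths run
171 → 85 → 71 → 35, flatten 560. Valid padding with floor-pooling is the
unique standard reading that reproduces both published parameter counts
(85,425 default; 2,332,385 for the wider 64/1024 variant), with one bias
per filter and per unit. The output layer is linear: the published
formulation applies ReLU to dense layers generally, but a ReLU head can
permanently zero the output; the parameter count is unaffected. Dropout
sits after the hidden activation and is active only in training (inverted
dropout), so inference is bit-deterministic. Training uses mean-squared
error, Adam at step size 1e-3, five epochs, batch 16, all randomness from
one seed. Inputs are raw signal values; standardization is available but
off by default. Only the stride-length target is implemented — the velocity
variant was reported inferior, and velocity follows as d/t anyway.

## The synthetic generator

The generator emulates the study conditions: running at 2–6 m/s sampled at
200 Hz, impact transients at initial contact, a near-zero-velocity
midstance, gravity embedded in the sensor frame, and configurable noise.
One stride cycle, anchored at the IC, is built from closed-form pieces in a
world frame (x lateral, y forward, z up):

* **Braking, 0–50 ms**: the foot lands with residual forward velocity
  $v_{land} = 0.4v$ still decelerating at $a_{land} = -8v$ m/s², and stops
  via a C¹ Hermite ramp. This matters for segmentation realism: the
  dorsoventral channel stays negative from late swing through the impact,
  as in real landings.
* **Plateau, to 250 ms**: the foot is exactly stationary (the ZUPT
  assumption holds by construction). A small pitch wiggle (rate
  $0.3\cos(\pi t/T_{st})$ rad/s) gives the gyroscopic energy a unique
  minimum exactly at midstance.
* **Swing**: a quartic velocity bump plus a Hermite tail carries the foot
  forward by the remaining stride length and returns it to
  $(v_{land}, a_{land})$ at the next IC, so acceleration is continuous
  across strides; a 12 cm vertical arc and a 0.5 rad pitch excursion
  complete the pose.
* **Impact**: a Hann-windowed 40 Hz sinusoid (peak 80 m/s², 50 ms) added to
  the forward *position* — not just the accelerometer — with a smoothstep
  correction that makes its net velocity and displacement exactly zero.
  Because its derivative vanishes at both ends, trapezoidal integration
  across it leaves only O(Δt⁴) residue, and ground truth is untouched.

Stride time follows a linear cadence model $t = 0.85 - 0.05v$ s (0.75 s at
2 m/s to 0.55 s at 6 m/s, in the range of published running cadences),
rounded to a whole sample count so the identity
$v_{ref} = d_{ref} f_s / N_{stride}$ holds exactly. Sessions prepend one
uncounted lead-in stride (so the first counted IC has a preceding swing
phase) and append a 0.3 s stance tail; impact transients are injected only
at counted ICs, so segmentation of a noise-free session finds exactly K
contacts, which yield K−1 midstance-to-midstance strides. Sensor noise
(Gaussian, defaults off; 0.3 m/s² and 0.02 rad/s in the noisy test
conditions) and a constant gyro bias are added last, seeded. Cohorts draw
heights from 178.6 ± 8.0 cm truncated to (1.5, 2.1) m, a 21:27 male
fraction, per-subject cadence offsets (σ = 0.02 s), and fill the velocity
bins 2–3, 3–4, 4–5, 5–6 m/s.

What the generator does **not** emulate: stride-to-stride kinematic
variability within a session (strides at one velocity are identical up to
noise), lateral foot motion, ground-reaction oscillations beyond the single
impact mode, treadmill-versus-overground differences, and fatigue. Passing
the round-trip tests therefore shows internal consistency of the algorithms
under idealized kinematics, not field accuracy on real runners. Two
specific consequences: the smoothed-peak step detector of the acceleration
method needs swing accelerations above its 30 m/s² threshold, which the
generator first produces near 2.4 m/s — slower sessions yield no steps for
that estimator; and the published headline accuracies depend on a
motion-capture dataset that is not deposited, so they are not reproduced
here.

## Numerical choices and study sizes

Trapezoidal integration is used for velocity and position (second-order,
matching the O(Δt²) consistency of the generator); the quaternion update is
the standard exponential map with per-step renormalization, which may
differ from other strapdown implementations at the sub-1e-3 rad level.
Midstance ties break to the earliest sample. The gravity-alignment
quaternion handles the antipodal case with a fixed 180° rotation about x.
Degenerate inputs (zero-length windows, single-sample summaries, all-equal
regression designs) raise errors rather than guessing.

The test suite runs the round-trip oracle on 25 sessions spanning 2–5 m/s
(200 strides) with and without noise, trains the CNN on 512 simulated
strides from 8 subjects and evaluates on 96 strides from 3 held-out
subjects, and uses 5 strides per simulated trial elsewhere; these sizes
keep the full suite under a minute of simulation plus a few seconds of
training while leaving the statistical margins wide (the observed
round-trip errors are an order of magnitude inside their bounds).

## Known limitations

* The stride-time tables are population averages; on the synthetic cohort
  (whose cadence model is not that population) the estimator is biased —
  which is precisely why it serves as the baseline the CNN must beat.
* The acceleration estimator is undefined below its step-detection floor
  (about 2.4 m/s under the generator's kinematics) and extrapolates poorly
  outside its training velocity range, as quadratics do.
* Trajectory accuracy rests on a genuine zero-velocity phase; at high
  speeds (and for forefoot strikers) real feet violate this more than the
  simulator does.
* The CNN is trained on simulator output only; nothing here claims
  generalization to real IMU data.
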