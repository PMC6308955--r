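# stridekit

Per-stride length and mean velocity estimation for running, from a six-axis
inertial measurement unit (IMU) embedded in a running-shoe midsole.

Runners and sports scientists want stride-resolved velocity and distance
without GPS. A foot-mounted IMU measures triaxial specific force
**a** (m/s²) and angular rate **ω** (rad/s) at a known rate (nominally
200 Hz); turning those signals into stride length d<sub>stride</sub> and
mean velocity v<sub>stride</sub> = d<sub>stride</sub>/t<sub>stride</sub> is
the job of this package. It implements and compares four estimators that
share a common stride segmentation:

1. **Stride time** — segment strides, take the duration
   t<sub>stride</sub> = N<sub>stride</sub>/f<sub>s</sub> between consecutive
   initial ground contacts, look up the gender-specific step function of
   relative stride length d<sub>stride,rel</sub>(t<sub>stride</sub>)
   (stride lengths per body height, from the running-biomechanics
   literature), and scale by the runner's height:
   d<sub>stride</sub> = h · d<sub>stride,rel</sub>.
2. **Acceleration** — accelerometer only: a sliding-window absolute
   integration value ι[n] = (L+1)⁻¹ Σᵢ Σ_d |s_d[n−i]| computed over the
   smoothed channels correlates with running speed and is mapped to
   velocity by a trained quadratic, v = A + B·ι + C·ι².
3. **Trajectory** — strapdown dead reckoning with zero-velocity updates
   (ZUPT): detect midstance as the gyroscopic-energy minimum within 250 ms
   of ground contact, initialize orientation from gravity, integrate the
   gyroscope with quaternions, rotate and subtract gravity, double-integrate
   with linear dedrifting so velocity is exactly zero at both midstances,
   and report the L2-norm of the final position as the stride length.
4. **Deep learning** — a small convolutional network (two valid
   convolutions with max pooling, one hidden dense layer with dropout, a
   linear output; 85,425 trainable parameters) regressing stride length
   from the raw zero-padded 6-channel stride window, trained for five
   epochs with batch size 16 under mean-squared error.

Segmentation finds initial ground contacts from the dorsoventral
acceleration: the squared difference signal H[n] = (a_y[n] − a_y[n−1])²
must exceed 1000 (m/s²)² and the backward swing-phase integral of a_y to
the previous zero crossing must fall below −3 m/s.

Because raw study data of this kind are rarely shareable, the package ships
a **synthetic stride generator**: closed-form foot kinematics (landing
brake, true zero-velocity stance plateau, smooth swing arc, pitch
excursion, near-Nyquist impact transient with exactly zero net
displacement) and the IMU signals they imply, exactly consistent with each
other. It provides ground truth for every estimator, and the evaluation
module supplies the usual agreement statistics (ME ± Std, MAPE, MAE,
Bland–Altman limits of agreement, leave-one-subject-out folds, cumulative
distance error with the convention error = reference − estimate).

## Worked example

```r
library(stridekit)

# Simulate a 10-stride run at 3.5 m/s with realistic sensor noise
cfg <- simulation_config(velocity = 3.5, accel_noise_sd = 0.3,
                         gyro_noise_sd = 0.02, seed = 42)
session <- simulate_session(cfg, n_strides = 10)

# Segment and reconstruct the foot trajectory stride by stride
est <- estimate_strides_trajectory(session$recording)
head(est[, c("stride_length", "stride_time", "velocity")], 3)
#>   stride_length stride_time velocity
#> 1      2.355426       0.675 3.489519
#> 2      2.364164       0.670 3.528603
#> 3      2.358863       0.685 3.443596

# Compare against the simulator's ground truth
gt <- session$ground_truth[seq_len(nrow(est)), ]
error_summary(gt$vref, est$velocity, "velocity")
#> velocity: ME -0.0001 +/- 0.0471, MAPE 0.98%, MAE 0.0341 (n = 9)
error_summary(gt$dref, est$stride_length, "stride_length")
#> stride_length: ME 0.0022 +/- 0.0024, MAPE 0.11%, MAE 0.0026 (n = 9)
```

The true stride length here is 2.3625 m (3.5 m/s × 0.675 s): the trajectory
estimator recovers it to a few millimetres per stride at these noise
levels. Ten simulated contacts give nine full midstance-to-midstance
strides; the first and last partial strides of a session are always
dropped.

A command-line entry point wrapping the same functions is installed at
`inst/cli/stridekit`:

```sh
Rscript inst/cli/stridekit simulate --subjects 2 --strides 10 --seed 1 --out sessions/
Rscript inst/cli/stridekit estimate sessions/S01_ses01_imu.csv --algo trajectory --out est.csv
Rscript inst/cli/stridekit evaluate --truth sessions/S01_ses01_gt.csv --est est.csv --out report.json
```

## Documentation

The methods vignette (`vignettes/stride-estimation.Rmd`) describes the
model assumptions, parameter defaults and units, what the simulator does
and does not emulate, numerical choices, and known limitations.
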