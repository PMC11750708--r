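---
title: "Models and methods in fingerbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fingerbci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingerbci)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, the parameters that matter, and the design
choices made where more than one reasonable implementation existed. The
package simulates the full computational stack of a finger-level
intracortical brain–computer interface (iBCI): synthetic neural signals,
closed-loop virtual-finger tasks, a neural-network velocity decoder with
intention-based retraining, an evaluation suite, and a quadcopter
control layer.

## The synthetic population

Real finger iBCIs record spike-band power (SBP) from ~192 microelectrode
channels; no generative model of that signal is available, only its use.
The package adopts the simplest model consistent with the theory it must
support: channel $c$ emits, per 50-ms bin,

$$x_c = b_c + \mathbf{t}_c^\top \mathbf{v}
      \;(+\; \mathbf{g}_c^\top \mathbf{p}(\mathbf{v}))
      \;+\; \varepsilon_c,
  \qquad \varepsilon_c \sim \mathcal{N}(0, \sigma_c^2)\ \text{i.i.d.},$$

where $\mathbf{v}$ is the finger velocity in range-of-motion (ROM) units
per second, $\mathbf{t}_c$ a per-channel tuning vector, and
$\mathbf{p}(\mathbf{v})$ the optional vector of pairwise velocity
products. Linear tuning with independent, identically distributed
Gaussian noise is exactly the ideal case assumed by the directional-SNR
channel-scaling theory (below), which makes the generator a calibrated
instrument rather than a convenience: the stack's headline prediction
($m = 0.5$) is known in closed form for what the generator emits. The
interaction terms are a deliberate nonlinearity knob — products of
independent zero-mean velocities are uncorrelated with the linear terms
and with each other, so their effect on population dimensionality is
also available in closed form (`analytic_participation_ratio()`), and
they reproduce, qualitatively, the super-linear growth of dimensionality
with simultaneously moving fingers.

Defaults: `tuning_sd = 1`, `noise_sd = 1`, `baseline = 1` (SBP units are
arbitrary; only relative structure matters downstream). No published
tuning-strength statistics exist for these channels, so the defaults are
a choice, kept configurable, with per-channel signal variance comparable
to noise variance under unit-speed movement — a regime in which single
channels are weakly informative and populations strong, as in practice.

What the generator does *not* emulate: spike waveforms or sorting, raw
30-kHz structure, slow nonstationarities and day-to-day instabilities,
correlated (shared) noise, and any refractory or history dependence.
Tests passing against this population therefore validate the *pipeline*
— estimators, training dynamics, bookkeeping — not robustness to real
neural data. One partial exception is behavioral noise:
`make_dsnr_dataset(motor_noise_sd = ...)` adds noise to the *executed*
velocity rather than to channels, producing the shared-noise ceiling
that makes empirical dSNR curves saturate and their log–log slopes fall
below the ideal 0.5.

## Tasks and the simulated user

Positions live in $u \in [0,1]$ per degree of freedom (DOF), neutral at
$u = 0.5$; the display convention $s = 2u - 1$ is a linear relabeling.
A single internal frame avoids sign errors between the flexion = 1 and
flexion = +1 conventions.

Open-loop cues use a minimum-jerk profile (2 s movement, 1 s hold —
40 + 20 bins at 50 ms). "Smoothly varying" does not pin down a profile;
minimum-jerk is the standard motor-control choice and has exactly zero
endpoint velocity and acceleration, which makes the cued labels
well-behaved at trial boundaries.

Closed-loop trials integrate the decoded velocity at 50 ms
(`u <- u + v·0.05`, clamped), and succeed when **all** DOF have been
inside their targets for a required hold of *consecutive* bins (500 ms;
1.5 s for the `t_train` variant), with any exit resetting the counter.
Whether a hold may be satisfied non-consecutively is not observable from
summary statistics; the consecutive-with-reset rule is the stricter
reading and is what makes "orbiting time" (re-approach after an exit) a
meaningful quantity. Trial timeout is 10 s (5 s for `t_train`). Default
target width is 0.20 ROM.

Random "out" targets are drawn uniformly in the active range
`[w/2, 1 − w/2]` and redrawn until they lie outside the central target,
so an out trial always demands movement; paired "back" trials return all
targets to center and inherit the same timeout. The `t_train`
bootstrapping variant alternates stationary all-center trials with
two-new-target trials, freezes the unselected finger group at center,
and snaps fingers back to center after every trial.

The simulated user is intentionally minimal: intent is the unit vector
toward the target (components zeroed inside a dead zone equal to the
target half-width), executed at a constant speed (`user_speed`, default
0.6 ROM/s) plus Gaussian motor noise (`motor_noise_sd`, default
0.05 ROM/s). A human in the loop predicts, procrastinates and learns;
this model does none of those, which is precisely why closed-loop
success rates here are upper bounds, not forecasts.

## The decoder

The network maps an $E_N \times 3$ window of SBP (three most recent
50-ms bins) to $d$ raw velocities:

1. a temporal feature layer, shared across channels, contracts the
   3 bins to 16 learned features per channel (a $3 \times 16$ weight
   matrix plus bias, applied channel-wise), followed by ReLU;
2. the flattened $16 E_N$ vector passes through four fully connected
   layers (defaults 256–256–256–$d$), ReLU after each except the last;
3. batch normalization and 50% dropout regularize every intermediate
   output (after each ReLU);
4. the final linear layer has **no bias**, and the final batchnorm
   learns **no bias** and applies **variance correction only** — the
   batch variance is computed about the batch mean, but no mean is ever
   subtracted, in training or inference. Any persistent output offset
   therefore survives into the loss and is penalized away during
   training, rather than being silently absorbed by an affine layer.

Raw outputs are converted to commands by
`v = gains · (raw − mean)/sd · speed_constant`, with mean and sd the
empirical statistics of the network's output on its training set, and no
smoothing. The per-DOF gain is "empirically tuned" in a real rig; here
it is auto-calibrated to the training-label standard deviation (so
decoded velocities come out in physical ROM-units/s) and can be
overridden with `set_gains()`.

Training: Kaiming-normal initialization (`sd = sqrt(2/fan_in)`, the
correct scale for ReLU stacks), Adam on the mean-squared error.
Velocity labels are standardized per DOF before the loss — consistent
with an output that is "ideally normalized" to zero mean and unit
variance — and the normalization statistics restore the physical scale
afterwards. Initial-training hyperparameters are not pinned by the
protocol this package follows (they live upstream of it); the defaults
are `lr = 1e-3`, 60 epochs, batch 64, all configurable. ReFIT updating
*is* pinned: starting from the online parameters, 500 Adam iterations at
`lr = 1e-4`, `weight_decay = 1e-2` on the relabeled set.

ReFIT relabeling assumes the user always intended motion toward the
target: per bin and per DOF the label keeps the decoded magnitude and
takes the sign of `target − position`; bins where a DOF sits inside its
target are labeled zero (the user was holding still — the emphasis the
`t_train` task places on stationary data), switchable off. Whether the
thumb's two axes should be relabeled as one 2-D vector (projecting the
decoded velocity onto the target direction) or per axis is genuinely
open; per-axis is the default and `mode = "vector"` provides the
alternative.

## Evaluation

*Online metrics.* Time to target is cue → first entry; acquisition time
is cue → final entry (the start of the successful hold, hold excluded);
orbiting time is their difference, so the three satisfy an exact
additive identity. Path-length efficiency is net displacement over
traversed path length (Euclidean norm over the cued DOF jointly),
which the triangle inequality bounds by 1; throughput is the Fitts
index of difficulty `sum over cued DOF of log2(D/W + 1)` divided by
acquisition time, the convention of the non-human-primate finger-BCI
literature (trials acquired instantaneously carry no information and
are excluded). Summary statistics are mean ± s.e.m. (sample
SD/`sqrt(n)`) over successful trials.

*Dimensionality.* The participation ratio
$(\sum_i \lambda_i)^2 / \sum_i \lambda_i^2$ of the mean-centered channel
covariance. For the linear generator it has a closed form, which the
empirical estimator must match — the package tests this agreement at
$10^6$ bins to within 2%.

*dSNR.* Each bin's intended direction $\mathbf{v}$ is a unit vector;
the predicted velocity decomposes into a signal component along
$\mathbf{v}$ (signed row-wise dot product) and an orthogonal noise
component, and
$\mathrm{dSNR} = \mathbb{E}[\|\hat{\mathbf{v}}_s\|] \big/
\sqrt{\operatorname{var}(\|\hat{\mathbf{v}}_n\|) +
\mathbb{E}[\|\hat{\mathbf{v}}_n\|]^2}$, the variance being the
population variance so the denominator is exactly the RMS orthogonal
component. The empirical pipeline fits PCA on the training folds only
(20 components — regularizing 192 channels down to a stable regressor
count), regresses the scores onto the intended directions, and
evaluates held-out predictions; six contiguous folds, deterministically
assigned. One upstream formulation reads as fitting the regression on
the *unreduced* training data immediately after constructing the
reduced version; this is treated as a typo and the regression is fit on
the PCA scores, which is the only reading under which the PCA serves
its stated regularizing purpose.

*Channel scaling.* dSNR is evaluated on random channel subsets at
counts from 5 to $E_N$ in steps of $E_N/20$ (rounded, deduplicated,
full count always included; $E_N/20 = 9.6$ is not an integer so
rounding is unavoidable), 25 subsets per count, and
$\log \mathrm{dSNR}$ is fit against $\log N_C$ on the highest 75% of
counts. For the ideal population the fitted exponent is 0.5; shared
motor noise bends the curve toward a ceiling and lowers the fitted
slope, which is the package's working model for why empirically
observed slopes fall in the 0.34–0.43 range rather than at the ideal.

## The quadcopter layer

Finger displacements map linearly to velocity commands — thumb flexion
→ forward, thumb abduction → right, index–middle → up, ring–little →
yaw — scaled by the empirically tuned per-DOF gains
(0.6, 0.8, 0.4, 0.6), the axis maxima (10 m/s linear, 90 deg/s yaw),
and clamped. The published description leaves the order of gain and cap
ambiguous; the gain is applied to the normalized displacement, then
scaled by the maximum, then clamped, so a gain of 0.6 yields 6 m/s at
full flexion. Sign conventions (e.g. whether index–middle flexion flies
up or down) are not printed anywhere and are configurable.

The "gravity" bias pulls a finger toward neutral with constant
magnitude (default 0.05 ROM/s, configurable — "low-amplitude" is not
quantified) whenever it is within 10% of ROM of neutral. A strictly
constant bias would overshoot neutral from positions closer than
`amplitude × 50 ms` and oscillate; within one step of neutral the bias
is capped at the value that lands exactly on neutral. Gravity is active
only in quadcopter mode (the finger tasks never mention it), switchable.

Flight uses first-order kinematics — velocity commands integrate
directly; there is no aerodynamic model, which matches the
velocity-level control semantics and keeps the layer exactly
reproducible. The translation is rotated at the *midpoint* heading of
each 50-ms step: end-of-step rotation is only first-order accurate and
visibly distorts turning flight (>3% radius error on a 90 deg/s turn),
while the midpoint rule is second-order and brings the same turn within
a fraction of a percent of the continuous solution. Ring crossing is
exact segment–disc intersection. The obstacle course (two rings on a
court, dimensions configurable) and the random-ring task (uniform
spawn box, near-horizontal orientations, 20-s per-ring timeout) are
parameterized builders, since the original course geometry is not
numerically specified.

## Numerical and degenerate-input conventions

* dSNR with zero decoded velocity on a bin: the angle is undefined;
  the bin contributes zero signal and zero noise. All-noiseless data
  yield `Inf` (flagged, not an error); no valid bins yield `NA`.
* `normalized_cc()` with a zero-norm trace returns `NA` for that DOF
  and averages the rest; the per-DOF values ride along as an attribute.
* A flat dSNR curve has zero log-variance: the power-law `R²` is `NaN`
  rather than a misleading 1.
* Batchnorm uses `eps = 1e-5` and momentum 0.1 on running statistics;
  minibatches of size 1 are skipped (batch statistics undefined).
* Labels with (near-)zero variance standardize with scale 1 to avoid
  division blow-ups.
* Serialization (JSON via jsonlite, `digits = NA`) round-trips doubles
  to ~10⁻¹⁵ relative precision — full double printing, not bit-exact.
* Every stochastic operation takes or derives an explicit seed;
  sessions, training runs, channel subsamples and flight logs are
  reproducible bit-for-bit under a fixed seed.

## Problem sizes

The test suite exercises the decoder and closed-loop machinery at
24–48 channels with 64-wide hidden layers and a few thousand training
bins — sizes at which every phenomenon of interest (recovery of a
linear code, ReFIT repair of a sign-flipped decoder, non-decreasing
success across retraining rounds) is already present. The
channel-scaling experiment runs at its full prescribed size: 192
channels, 5,000 bins, 25 subsets per count. The dimensionality oracle
comparison uses 10⁶ bins.

## Known limitations

* The population model is stationary and noise is independent across
  channels; none of the drift/instability phenomenology of chronic
  recordings is represented, so retraining here demonstrates mechanism,
  not necessity.
* The simulated user is memoryless and reactive; human anticipation,
  fatigue and learning are absent, and closed-loop metrics should be
  read as pipeline diagnostics, not performance predictions.
* Throughput and normalized-CC conventions follow the cited literature
  where the governing definitions are not printed in full; both are
  configurable at the call site.
* The quadcopter is kinematic; course times are not comparable to a
  physics-simulated vehicle.
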