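---
title: "Population formatting, two-stage recurrent models, and in-silico perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population formatting, two-stage recurrent models, and in-silico perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Sensory and cognitive variables can typically be decoded from almost any
brain area, so the mere presence of information says little about what an
area does. A sharper question is how variables are *formatted* in the
population code: in a space where each unit's activity is one dimension,
two variables may occupy orthogonal subspaces (separable formatting) or
overlapping ones (joint formatting). `popformat` implements a complete,
simulation-based pipeline for studying the link between formatting and
function in a continuous perceptual decision task with reward-scaled
choices, modeled on the comparison between the middle temporal visual
area (MT, motion-selective) and dorsolateral prefrontal cortex (dlPFC,
decision- and reward-related):

1.  a reward-scaled direction-estimation task (`reward_profile()`,
    `expected_reward()`, `sample_trials()`);
2.  a gain-modulated tuning simulation showing that identical single-unit
    tuning is compatible with either formatting (`tuning_theta_sweep()`);
3.  a two-stage recurrent network with a sensory module trained to report
    motion and reward-condition inputs separably and a decision module
    trained to predict the expected reward of every candidate choice
    (`train_two_stage()`);
4.  fixed-point analysis of the trained dynamics
    (`module_fixed_points()`, `project_points()`);
5.  a formatting-angle statistic and paired across-session comparison
    (`formatting_angle()`, `compare_areas()`);
6.  synthetic recording sessions with exact ground-truth formatting
    angles (`generate_session()`);
7.  in-silico microstimulation with regime classification
    (`run_perturbation_experiment()`, `classify_regime()`,
    `offset_sweep()`).

## The task

On each trial a motion direction and a reward condition are drawn
independently. A choice `x` earns

    reward(x) = exp(kappa * (cos(x - motion) - 1)) * scale(x)

where the von-Mises-shaped accuracy kernel rewards precise direction
estimates and `scale(x)` is 2 inside a 45-degree half-width region around
the increased-reward center, 0.5 inside the antipodal decreased-reward
region, and 1 elsewhere (all configurable; a soft-edged variant exists).
The two trained reward conditions place the increased center at 45 or 225
degrees.

The kernel concentration defaults to `kappa = 4`, i.e. the accuracy
reward halves at roughly 30 degrees of error. This value was chosen on
two grounds. First, the task is a precision task: with a much flatter
kernel (kappa below about 1) the reward landscape is so shallow that the
reward-maximizing policy jumps into the increased region even when the
motion evidence points 130 degrees away, and choices stop tracking
motion. Second, with a flat kernel the expected-reward profile over
candidate choices has bumps so broad that two competing reward peaks
blend into one, and the discrete choice-switching phenomenology of the
decision module (below) cannot exist. With `kappa = 4` the
reward-maximizing choice equals the motion direction far from the scaled
regions, and is pulled toward the increased region for
motion-to-center offsets up to about 80 degrees (e.g. at a 60-degree
offset the maximum sits at the region edge, strictly between the motion
direction and the center).

## The gain-modulated tuning simulation

`build_population()` makes 36 von Mises tuned units with preferred
directions every 10 degrees. Reward modulation multiplies the tuned
component of each unit by a gain whose mean interpolates from 1.3 (unit
preference at the increased-reward center) to 0.8 (antipodal), plus
heterogeneity. The heterogeneity is *coordinated*: a smooth random
function of preferred direction built from 3 random Fourier harmonics
with marginal SD 0.35. This is the population-level knob the simulation
is about — whether and how reward modulation is coordinated across the
population, not single-unit statistics, decides the formatting. With
independent per-unit noise (available as `noise_harmonics = 0`), the
formatting angle concentrates in a narrow mid-range band and the
simulation cannot produce clearly separable or clearly joint draws; with
coordinated noise the same single-unit tuning and the same marginal gain
distribution produce draws anywhere from theta below 10 degrees (joint)
to near 90 degrees (separable). `coordination = "orthogonalized"`
deterministically projects the between-condition gain difference out of
the motion plane, guaranteeing a separable example.

## The formatting angle

`formatting_angle()` operationalizes "the dimensions carrying the most
variance": the *motion plane* is the top-2 principal plane of the
direction-binned means (averaged across reward conditions); the *reward
axis* is the normalized difference of the two condition means (averaged
across directions); and

    theta = acos(|| projection of the reward axis onto the motion plane ||)

lies in [0, 90] degrees: 90 = fully separable, 0 = fully joint. The
estimator is isolated behind one function; an axis-vs-axis variant
(`method = "axis"`) is provided because a one-dimensional reading of the
motion dimension is also defensible. theta is invariant to unit
relabeling, global rotations of unit space, and uniform scaling; the
plane-based default is the package's primary statistic throughout.
Angles across sessions are compared with a paired Wilcoxon signed-rank
test; for 25 or fewer pairs the exact sign-flip distribution of the
mid-rank statistic is computed by dynamic programming (ties allowed),
above that the usual normal approximation is used.

## Synthetic recording sessions

`generate_session()` injects the geometry by construction: direction
means lie on a ring of radius `motion_signal_scale` in a random 2-D plane
of unit space, and the two conditions are offset by
`reward_signal_scale` along a unit vector at exactly `true_theta_deg` to
that plane; counts are Poisson (or Gaussian, or noise-free). Because the
construction lives in mean space, theta recovery has an exact oracle: the
estimator applied to noise-free sessions must return the construction
angle. The default preset — 36 units, 20 trials per (direction,
condition) cell, baseline 10, motion scale 12, reward scale 10
spikes/trial — was calibrated once so that single-trial decoding is
comfortably above chance (condition accuracy about 0.88, direction MAE
about 18 degrees with a 5-fold nearest-centroid decoder) while
single-session angle estimates remain visibly noisy (SE about 1 degree at
mid-range angles). The generator emulates independent Poisson counts
only; real cortical populations have correlated variability that can
bias subspace estimates, so passing tests here demonstrate estimator
correctness, not robustness to correlated noise.

## The two-stage recurrent model

Both modules are discrete-time leaky firing-rate networks,
`x' = (1 - alpha) x + alpha tanh(W x + U u + b)`, with 64 hidden units,
leak 0.1, and 40 timesteps per trial. Inputs are 6 channels: motion as a
(cos, sin) pair scaled by coherence with i.i.d. Gaussian per-timestep
noise of SD `0.5 * (1 - coherence)`, and the two reward centers as clean
(cos, sin) pairs. Reward-center channels are on from trial start; motion
is on during timesteps 6–30 only, followed by a 10-step delay:

*   the **sensory (MT-like) module** is trained (mean-squared error,
    Adam, backpropagation through time) to output motion direction and
    both center locations as separate (cos, sin) channel pairs at the
    *end of the stimulus epoch* — a stimulus-locked, separable output
    parameterization;
*   its weights are then frozen, and the **decision (dlPFC-like)
    module**, which receives the sensory module's motion output channels
    (run in the loop) plus the center channels, is trained to output the
    expected reward of each of 36 candidate directions at the *end of
    the trial*, across the delay. The model's choice is the candidate
    with the largest predicted reward (ties to the lowest index).

The stimulus-offset/delay structure matters: if both modules read out
while the stimulus is present, both are input-pinned and every
perturbation produces graded, averaging effects. With the delay, the
decision module must hold its decision in recurrent attractor states,
which is what makes discrete perturbation outcomes possible, and is the
package's model of the sensory/decision division of labor.

Training hyperparameters (Adam learning rate 2e-3, 400 epochs of 512
trials, batch 128, L2 penalties on activity, weights, and output weights)
are exposed in `rnn_config()`. The output-weight ridge is not cosmetic:
it pulls the readout toward the minimum-norm, population-vector-like
solution in which a unit's readout contribution aligns with its tuning —
the property that makes activating a unit move the readout toward that
unit's preference, as electrical microstimulation does. Training is gated
on behavior, not on hyperparameters: the sensory module must reach a
held-out circular MAE of 10 degrees on the decoded motion direction
(about 9 degrees typical; the mixed-coherence ideal observer is near 8)
and the decision module a median per-trial Pearson correlation of 0.9
between predicted and true reward profiles (about 0.94 typical). A
training run that misses its gate carries `converged = FALSE` and warns;
at this network scale roughly one seed in three misses the sensory gate
by up to a degree, which is reported rather than hidden.

Problem sizes throughout (64 units, 40 timesteps, 400 epochs, 5 training
seeds in the test suite, 3 in the acceptance script) are the package's
default desk scale: one two-stage training run takes a couple of minutes
on one CPU core.

## Fixed points

`find_fixed_points()` iterates the dynamics under the constant input of
one (direction, condition) pair from end-of-trial states plus random
restarts, polishes with damped Newton on `||F(x) - x||`, deduplicates by
single-linkage clustering at a radius of 1e-3 times the state RMS (with
a floor of 100 times the speed tolerance, default 1e-8), and verifies
stability through the Jacobian spectrum (`assess_stability()`). Merged
slow-manifold points are collapsed and counted. The trained sensory
module yields one stable fixed point per (direction, condition) pair,
arranged as a direction-ordered ring in the motion plane
(`ring_topology()`), with the two reward conditions' rings close to each
other — the geometric signature of separable formatting. The decision
module's trial-end states separate reward conditions more, i.e. a
smaller formatting angle; across training seeds the sensory module's
theta (about 85 degrees) reliably exceeds the decision module's (about
73–82 degrees). The formatting dichotomy in this model is therefore
real but quantitative rather than the qualitative separable-vs-joint
contrast seen in cortex; small networks trained with clean center input
channels have little pressure to entangle reward deeply into the motion
code.

## In-silico perturbation

Microstimulation is modeled as an additive constant drive to the
pre-activation of a *site*: the seed unit plus all tuned units whose
preference lies within 30 degrees (a single electrode activates a
cluster of similarly tuned neurons; `site_width = 0` recovers a
single-unit perturbation, whose effect in a 64-unit tanh network
saturates at a few degrees of readout shift and is too weak to study).
The site's preference is the activity-range-weighted circular mean of
its members — the analog of multiunit tuning on the electrode. Default
epochs are module-specific: the sensory module is perturbed while the
stimulus is on (its period of influence), the decision module from late
stimulus through the delay, released before the readout window so the
attractor settles before the choice is read.

Experiments use the two trained reward conditions, like the task itself:
for a unit whose preference falls inside the scaled region of one
center, one condition is the *increased-aligned* class and the antipodal
condition the *decreased-aligned* class; units outside both regions are
*neutral*, and their experiments interleave both conditions. The drive
strength is calibrated per module so the mean choice shift at a
60-degree offset under neutral alignment is about 20 degrees
(`calibrate_perturbation()`).

`classify_regime()` distinguishes outcomes by maximum-likelihood von
Mises mixture fits (1 vs 2 components, BIC margin 10, EM with fixed
deterministic restarts): *vector averaging* = one mode strictly between
the reference point and the site preference (10-degree guard bands);
*winner take all* = two modes within 25 degrees of the reference and the
preference respectively, with less than 10% of choices within 30 degrees
of the midpoint; otherwise no-effect/other. Choices from an argmax over
36 candidates are quantized to 10 degrees, so the classifier adds
deterministic half-bin jitter before fitting and treats two modes closer
than twice the mode tolerance as one. The reference point is the mean
control choice of the same condition, which on aligned trials already
sits slightly off the motion direction.

What the trained model reproduces, and what it does not:

*   Perturbing sensory-module sites shifts choices unimodally toward the
    site preference — vector averaging. The regime extends to large
    offsets: per-seed sweep limits fall between 150 and 180 degrees
    (pooled majority typically 160–170), slightly beyond the
    approximately-150-degree boundary one might expect, because at the
    calibrated strength the drive produces near-complete yet still
    unimodal capture (perturbed modes land within about 30 degrees of
    the preference) rather than petering out. The effect barely depends
    on the reward condition.
*   Lowering motion coherence amplifies perturbation effects in both
    modules without changing their character.
*   Perturbing decision-module sites interacts with the reward
    condition: the effect is larger when the site's preference carries
    the increased reward, and the median interaction index exceeds
    twice the sensory module's.
*   At sub-calibration drive strengths the decision module produces
    genuinely bimodal outcomes — on some trials the control choice, on
    others a jump, with essentially no mass in between. However, the
    jump lands at the near edge of the increased-reward region (about
    60 percent of the way to the preference for a 100-degree offset)
    rather than at the preference itself, and at the calibrated strength
    capture is near-total and the distribution unimodal. The strict
    winner-take-all classification (both modes at the anchors) is
    therefore usually not met at this network scale: the delay-period
    attractors of a small decision module form at reward-profile peaks,
    and full capture to the preference occurs only far above
    calibration. This limitation is reported as-is by the test suite.

## Reproducibility and numerical choices

Every stochastic function takes a `seed` and isolates its RNG from the
caller; training is bit-for-bit reproducible given (config, seed).
Pipeline stages (`reproduce()`) derive named sub-seeds from the global
seed and write them, with a configuration hash, into a `manifest.json`
next to every output. Checkpoints are JSON; sessions and tables are CSV.
Ties in the choice argmax go to the lowest candidate index; angles are
degrees, counterclockwise, reduced to [0, 360); theta is averaged
arithmetically across sessions (it is bounded, not circular). Degenerate
inputs (rank-deficient means, identical conditions, untuned units,
non-converged fixed points, overlapping reward regions) raise errors or
flags rather than propagating silently.
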