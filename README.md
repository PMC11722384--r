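# popformat

Neural populations almost always carry decodable information about many
variables at once, so *what* an area encodes says little about what it
does. What differs between areas is the **formatting** of that
information: in the space where each unit's activity is one dimension,
two variables can occupy orthogonal subspaces (separable) or overlapping
ones (joint). `popformat` is a simulation and analysis toolkit for
linking population formatting to function in a continuous, reward-scaled
direction-estimation task, modeled on the contrast between a sensory
area (motion-selective, MT-like) and a decision area (reward-integrating,
dlPFC-like).

The package implements, end to end:

- **Task model** — trials combine a motion direction with a reward
  condition; a choice `x` earns
  `exp(kappa (cos(x - motion) - 1)) * scale(x)`, where `scale` is 2
  inside the increased-reward region of the target ring, 0.5 inside the
  antipodal decreased region, and 1 elsewhere.
- **Gain-modulated tuning simulation** — identically tuned von Mises
  units with coordinated reward-gain heterogeneity; the same single-unit
  statistics produce population codes anywhere from separable to joint.
- **Formatting angle** `theta` — the angle between the axis carrying the
  most reward-condition variance and the plane carrying the most
  motion-direction variance (90° = separable, 0° = joint), with a paired
  exact signed-rank comparison across sessions.
- **Synthetic recording sessions** — Poisson populations with the
  formatting angle injected by construction, so the estimator has an
  exact oracle.
- **Two-stage recurrent network** — a frozen sensory module trained to
  report motion and reward-center inputs separably feeds a decision
  module trained to predict the expected reward of all 36 candidate
  choices; the model's choice is the reward argmax. Training is
  hand-rolled backpropagation through time with Adam, bit-for-bit
  reproducible from a seed.
- **Fixed-point analysis** — stable fixed points of each trained module
  per (direction, condition), with ring-topology checks and
  motion-plane / principal-component projections.
- **In-silico microstimulation** — additive drive to a tuned site,
  matched-noise control trials, perturbation-minus-control choice maps,
  and a von Mises mixture classifier separating *vector averaging*
  (choices shift smoothly between motion and the site's preference) from
  *winner take all* (bimodal choices, never in between), plus
  reward-alignment and coherence interactions.

## A worked example

```r
library(popformat)

# a synthetic session with a known 45-degree formatting angle
g  <- generate_session(session_spec(true_theta_deg = 45), seed = 7)
fa <- formatting_angle(g$session)
dc <- decode_check(g$session)

# identical single-unit tuning, 50 heterogeneity draws
sw <- tuning_theta_sweep(50, seed = 7)

# fifteen paired sessions from a separable and a joint "area"
pairs <- generate_area_pair(15, c(75, 85), c(35, 45),
  session_spec(n_units = 16, n_trials_per_cell = 5,
               directions = seq(0, 330, 30)), seed = 7)
est <- t(vapply(pairs, function(p)
  c(formatting_angle(p$a$session)$theta_deg,
    formatting_angle(p$b$session)$theta_deg), numeric(2)))
cmp <- compare_areas(est[, 1], est[, 2])
```

This prints (via the obvious `sprintf` calls):

```
estimated theta: 45.2 deg (truth 45.0)
condition accuracy: 0.87 (chance 0.50); direction MAE: 17.9 deg
tuning sweep: theta range 19.7-82.7 deg; 4/50 draws > 70 (separable), 23/50 < 45 (joint)
paired comparison: mean theta 80.3 vs 41.9 deg, signed-rank p = 6.1e-05
```

The session's angle is recovered within sampling error and both task
variables decode well above chance; across gain draws the same tuning
curves span both formatting regimes; and the paired design separates the
two areas at the exact signed-rank floor for 15 sessions.

Training and perturbing the network model:

```r
model <- train_two_stage(rnn_config(), seed = 1)     # ~2-3 min on 1 CPU
units <- tuned_units(model, "mt_like", 5, "neutral")
s     <- calibrate_perturbation(model, "mt_like", units)
sweep <- offset_sweep(model, "mt_like", units, strength = s)
sweep$va_limit_deg   # largest offset still classified vector averaging
```

`reproduce()` (or the `inst/cli/popformat` script) writes the data tables
behind each figure-style analysis — tuning sweep, synthetic paired
sessions, model behavior, fixed points, perturbation maps — together
with a manifest of every sub-seed used.

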