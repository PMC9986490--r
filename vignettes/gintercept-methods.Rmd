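---
title: "Active inference for locomotor interception: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active inference for locomotor interception: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task

An agent travels along a straight path toward an invisible interception
point while a target approaches the same point on a converging straight
path. The simulation runs at 60 Hz. The agent starts from rest at a
distance drawn uniformly from 25–30 m and controls its speed only through
a pedal with six positions mapping to speeds {2, 4, 8, 10, 12, 14} m/s via
a first-order lag: one step changes the speed by `K (V_p - v_s)` with
`K = 0.017` (a sluggish-vehicle condition halves `K`). The target starts
at one of three speeds {11.25, 9.47, 8.18} m/s and, at an onset drawn
uniformly from 2.5–3.25 s, ramps linearly over 500 ms to a final speed
drawn from N(15, 5²) truncated at ±1 sd. Because the final-speed mean
exceeds every initial speed, the target usually accelerates: an agent that
only matches the *current* kinematic requirement tends to arrive late.

Two quantities are not part of the published task statistics and are
package design choices, fixed once and logged with every run: the target's
initial distance (45 m, which puts its first-order time-to-contact at
4.0–5.5 s so that the speed change falls partway through the approach) and
the success criterion (agent and target simultaneously within a 1 m
capture radius of the point; the episode otherwise ends when the target
passes 1 m beyond the point or after 15 s). The observation is the raw
4-vector ⟨target distance, target speed, agent distance, agent speed⟩ with
no sensory noise; positions are scalar distances to the point, so no
bearing-angle geometry is simulated.

## The agent

The agent learns an action value `G(o, a)` — the negative expected free
energy of taking pedal `a` at observation `o` — with a two-headed
multilayer perceptron: a shared ReLU trunk (default 128 × 128), a linear
head with one G-value per action, and a linear head predicting the next
observation. Actions are chosen greedily on G. The per-step reward that
defines G combines:

* an **instrumental** term: the log-likelihood of the outcome under a
  Gaussian prior preference (sd 1 m/s, normalizer dropped) over the *speed
  difference* — the speed the agent is steering toward minus the speed
  required to reach the point at the target's first-order time-to-contact,
  `x_s v_t / x_t`;
* an **epistemic** term: the squared prediction error of the transition
  head on the realized next observation, an exploration bonus that decays
  as the forward model converges.

Learning follows the standard replay construction: transitions
`(o, a, r, o', terminal)` go to a 10⁵-capacity FIFO buffer; each
environment step samples a uniform minibatch and applies one Adam update
on the summed quadratic losses of the two heads (both with unit output
variance). The G-head target for the taken action is
`r + γ max_a G_frozen(o')` through a target network synchronized every
2,000 updates, zero bootstrap at terminal transitions; non-taken actions
keep the online estimates so only the taken action carries error.

### The prior space and the speed placed in it

The prior mapping collapses the 4-D observation to the one-dimensional
speed difference. The speed entered into this difference is, by default,
the **pedal speed of the selected action** — the speed the agent is
steering toward — rather than the realized lagged speed
(`prior_config(speed_source = "realized")` selects the latter). The
choice matters: one lag step moves the realized speed by at most
`0.017 × 12 ≈ 0.2` m/s, so under the realized reading all six actions
collapse onto nearly the same point of the prior axis and the per-action
instrumental contrast is ~1% of the reward's state-dependent baseline —
too small for a value network to discriminate actions reliably. Under the
pedal reading the six actions spread across the prior axis at their pedal
positions, the myopic (γ = 0) policy reduces to the first-order
required-speed tracker, and the interesting behavior — anticipation — has
to be bought by the discounted bootstrap, which is exactly the contrast
the analyses probe.

Two numerical guards that the idealized formulas need: the required speed
`x_s v_t / x_t` diverges as the target closes on the point, so the speed
difference is clamped at ±8 m/s (bounding the reward below at −32 and
keeping rare end-of-episode transitions from dominating the quadratic
loss — with a ±20 clamp those outliers are weighted 10⁴ times a typical
residual and visibly destabilize training); and the terminal transition of
a successful episode is scored at the prior's mode (difference 0), since
"arrive together" is precisely the preferred outcome and the required
speed is degenerate there. Misses fall through to the clamped formula,
which automatically yields the maximum penalty once the target has passed.

### Scales and normalization

Observations are divided by (50, 20, 50, 20) — distances by 50 m, speeds
by 20 m/s — before the network and inside the epistemic norm, keeping both
loss heads on O(1) inputs and making the epistemic bonus commensurate with
instrumental rewards of a few units. The epistemic term is computed in
these normalized units with weight 1.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| discount γ | 0.99 | the far-sighted condition of the study; 0 gives the myopic/reactive condition |
| trunk | 128 × 128 ReLU | smallest round width that solves both the toy-MDP oracle and the task |
| learning rate | 5e-4 decaying linearly to 1e-4 over 4 × 10⁵ updates | a constant 1e-4 had not converged by 3,000 episodes, a constant 5e-4 oscillated late; the decay keeps the fast early rise and the stable plateau |
| batch | 32 | the canonical replay minibatch for this construction |
| target sync | every 2,000 updates | ~8 episodes; less frequent syncing visibly reduced late-training oscillation relative to 1,000 |
| replay capacity | 10⁵ | as specified for the replay buffer |
| warm-up | 1,000 transitions | ~4 episodes of experience before the first update |
| prior sd | 1 m/s | symmetric single-peaked preference over speed difference |
| speed-difference clamp | ±8 m/s | reward floor −32; see above |
| epistemic weight | 10 | in normalized units. The deterministic dynamics are learned quickly, so the bonus must be an order of magnitude above the raw squared error to act as a usable exploration drive early in training; calibration runs at weight 1 were markedly more seed-sensitive (final-window success sd ≈ 0.09 across three seeds versus ≈ 0.01 at weight 10). The bonus still decays toward zero as the forward model converges, so late-training rewards are dominated by the instrumental term. 0 gives the instrumental-only ablation |
| exploration ε | 0 (AIF) | greedy action selection; optimistic zero initialization plus the epistemic bonus supply exploration. The DQN baseline uses 1 → 0.05 linearly over 500 episodes |

Weight initialization is He-style normal for the trunk and `1/fan-in`
normal for the heads, biases zero. The compiled training path runs in
single precision (a trial is ~7.5 × 10⁵ minibatch updates); all
single-precision components are cross-checked in the test suite against
double-precision reference implementations of the forward pass, the
bootstrap targets and finite-difference gradients.

## Baselines

The DQN baseline shares the trunk and G head, disables the transition
head's loss, learns from the sparse terminal reward (success 1, miss 0 —
so its episode return *is* its success indicator) and explores
ε-greedily. The instrumental-only ablation is the full agent with the
epistemic weight set to zero; every other code path is shared.

## Analyses

Each episode logs the outcome together with the state at the moment the
target's speed change begins. From that state three times-to-contact are
computed: the agent's first-order TTC `x_s / v_s`, the target's
first-order TTC `x_t / v_0`, and the target's actual TTC through the
realized ramp (closed-form quadratic on the ramp segment, verified in the
tests against 60 Hz integration). Post-convergence episodes (after
episode 1,500 by default, where training stabilizes) are grouped by
target initial speed and summarized as Tukey boxplot statistics. The
**anticipation index** locates the agent's median TTC on the segment from
the target's first-order median (0 = reactive) to its actual median
(1 = fully anticipatory); the overall index averages the three groups.
A purely reactive agent tracks the first-order requirement and scores
near 0; an agent that accounts for the likely future acceleration leaves
earlier and scores toward 1.

## What the simulator does and does not emulate

The generator reproduces the published episode statistics exactly
(initial distances, the three initial speeds, onset window, truncated
final-speed distribution, ramp duration, 60 Hz update). It does not
render the visual scene: there is no optic flow, no bearing angle, no
sensory noise, and no visuo-motor delay. Tests passing on this simulator
therefore show that the *learning architecture* produces reactive versus
anticipatory control as the discount factor and vehicle responsiveness
vary — not that the model explains human perceptual information use.

## Problem sizes used in the checks

The packaged checks train one full-scale trial (3,000 episodes) per
condition of interest and three-seed replications at 1,500–3,000 episodes
(the study itself used 20 trials per condition); evaluation uses 200
frozen-policy episodes. The toy-MDP oracle check uses a 3-state,
2-action deterministic MDP at γ = 0.9 solved by value iteration, with the
learned G-values required to match within 10⁻².

## Known limitations

* Learned performance is seed-sensitive: with greedy action selection the
  early value estimates steer data collection, and unlucky early episodes
  can lock the agent into a mediocre policy for the rest of a 3,000-episode
  trial. Across probed seeds the final-window success of the full agent
  spans roughly 0.55–0.95. The epistemic bonus (and its weight) is the
  mechanism that counteracts this; stronger weights showed diminishing
  returns.

* Success rates depend on the two configurable task constants the source
  material does not print (target initial distance, capture radius);
  results are reported under the defaults above.
* The G head's action contrasts shrink as `K` decreases; very small lag
  coefficients would need longer training or coarser action sets.
* Checkpoints restore weights and counters but not optimizer moments or
  buffer contents; resumed training is statistically, not bitwise,
  equivalent.
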