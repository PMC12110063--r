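---
title: "Modeling attentional dynamics in focused-attention meditation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling attentional dynamics in focused-attention meditation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipassim)
```

## The model

`vipassim` simulates focused-attention meditation as a three-level
agent-based dynamical system. At the bottom, five *thoughtseeds* — competing
attentional agents (`breath_focus`, `equanimity`, `pain_discomfort`,
`pending_tasks`, `self_reflection`) — carry continuous activations
α ∈ [0, 1]. In the middle, four *meditation states* act as attractor basins
over the activation space; the system's current state conditions the
activation dynamics, and state changes emerge from the dynamics rather than
from a scripted cycle. At the top, scalar *meta-awareness* μ monitors the
network and feeds back into the activation targets.

Each timestep represents one second, so dwell statistics in timesteps read
directly as seconds.

### Attractor landscapes

Each state is defined by which thoughtseeds support it: `breath_control` by
`breath_focus` (primary) and `equanimity` (secondary); `mind_wandering` by
the two distractions; `meta_awareness` by `self_reflection`;
`redirect_breath` by `equanimity` and `breath_focus` jointly. The
state-weight matrix W draws each entry uniformly from ω·[0.9, 1.1]
(primary), ω·[0.7, 0.9] (secondary) or ω·[0.05, 0.2] (otherwise), with
ω = 1 so weights read directly as activation targets.

### Training phase

`train()` runs a rule-based loop (default 200 steps) in which

* activations blend toward the current state's (modulated) weight row:
  α(t+1) = (1−γ)·α(t) + γ·α_target + Δα_dist + η, γ = 0.1;
* distraction thoughtseeds spike spontaneously (probability 0.10 per step
  for novices, 0.03 for experts; amplitude uniform on [0.2, 0.4]);
* during `mind_wandering` with μ < 0.6 the `breath_focus` target collapses
  (×0.05) while distraction targets are amplified (×1.2) — the modeled
  attentional lapse;
* μ is re-set each step by a five-branch state-dependent rule whose
  zero-noise values are 0.55 (distracted wandering), 1.0 (wandering with a
  non-distraction winner, i.e. detection), 0.85 (redirection), 0.75 (breath
  control) and 0.9 (meta-awareness); every branch keeps μ ≥ 0.55;
* the current state's weight row is nudged toward the observed activations
  by the 90/10 momentum rule, entries clipped to [0, 1.1ω];
* state transitions (below) are recorded into transition counts, the
  row-stochastic matrix T, and per-pair mean transition activations.

The noise law is Gaussian with sd `noise_scale` by default; a uniform
±`noise_scale` alternative is available via the profile's `noise_law`
switch, since only boundedness of the noise is essential to the model.

### State transitions

Transitions are hybrid:

* **Natural:** another state j captures the trajectory when its attractor
  support φ_j (the mean activation over its primary + secondary
  thoughtseeds) exceeds the threshold θ = 0.45, *and* strictly exceeds the
  current state's own support, once a minimum dwell has passed. The strict
  dominance condition is a deliberate design choice: `breath_control` and
  `redirect_breath` share the same attractor set, so a pure threshold rule
  would bounce the system between those twin basins every few steps and the
  four-state cycle would never form. Requiring φ_j > φ_current makes
  capture mean what it should — the evidence for the other basin dominates —
  and yields the intended rest behavior (a noise-free run started in
  `breath_control` stays there forever).
* **Forced:** each episode draws a dwell cap from the state's
  N(mean, sd) rounded and clipped to [mean − 2·SD, mean + 2·SD] (never
  below 3 steps); reaching the cap without a natural transition forces an
  exit sampled from the packaged empirical reference row (training) or the
  learned T row (simulation), renormalized over its off-diagonal.

Dwell parameters are part of the expertise profile: `mind_wandering`
25 ± 5 steps for novices and 10 ± 2 for experts, all other states 10 ± 3.
These are the study conditions, not tuning knobs: together with the
episode-level cap sampling they encode the empirical episode bands
(novices wander 20–30 s, experts 8–12 s). Using only the hard cap
mean + 2 SD as the forced trigger would distort both bands upward, which is
why the cap is sampled per episode; the lower bound mean − 2 SD doubles as
the natural-transition dwell minimum.

### Reference transition matrices

The packaged 4×4 reference matrices summarize empirical transition
probabilities for each level. Published sources report only some entries of
each row (e.g. experts stay in breath control 55% of the time and move to
meta-awareness 25%); the remaining mass of each row is split equally over
the unreported entries. Every entry carries a provenance flag (`printed` or
`filled`), and analyses should only lean on printed entries — the fill is a
package choice made solely so rows are proper distributions.

```{r}
reference_transition_matrix("expert")
```

### Interaction-network extraction

`extract_network()` recovers a signed 5×5 influence network from an
activation trace in three stages. For every ordered pair, one least-squares
autoregression of the target on its own 5 lags is compared with one adding
5 lags of the source; the statistic is the relative RSS reduction and the
p-value comes from the likelihood-ratio χ²₅ test. (The alternative reading
of the statistic — one regression per lag, summed — is noted as ambiguous
in the formulation; a single L-lag regression is the standard construction
and is what the package fits.) Significant pairs (p < 0.05) are calibrated
to magnitudes (1 − p/0.05)·0.7, a linear map chosen for transparency (a
−log₁₀ alternative is available via `map = "log10"`); signs come from the
summed cross-lag coefficients and sub-0.1 magnitudes are filtered. Finally
W = 0.7·causal + 0.3·zero-lag correlation, entries with |W| ≤ 0.15 are
zeroed, and the survivors are rescaled by a single global factor
min(1, 0.6/max|W|) — a ratio-preserving scale rather than per-entry
clipping, so relative edge strengths survive the bound.

### Simulation phase

`run_simulation()` runs the trained model under momentum dynamics: each
thoughtseed moves toward a Wilson–Cowan-style target
W[state, i] + (Σ_j W_net[j,i]·α_j)·τ + bias(state, i)·τ + μ·β_i at its own
responsiveness r_i (drawn once per run from the profile's band). The state
bias is +0.1 on a state's attractor thoughtseeds (the formulation calls for
state-specific baseline modulation without printing values; a small uniform
attractor bonus is the least-structured choice), τ = 1 by default (a single
gain is used for both the interaction sum and the bias, the two appearances
being treated as one configurable quantity), and β couples μ into targets
(+0.3 for self_reflection and equanimity, −0.2 for distractions, +0.1 for
breath_focus — signs follow the described top-down effects of awareness).
Dominance is winner-takes-all with ties broken by canonical thoughtseed
order. Transitions reuse the hybrid rule with the learned T rows,
falling back to the reference row for states never exited in training —
a 200-step training run does not populate every row.

## Parameters at a glance

| Parameter | Meaning | Default |
|---|---|---|
| `noise_scale` | activation noise sd | 0.08 novice / 0.04 expert |
| `meta_noise_scale` | μ noise sd | 0.03 |
| `momentum_gamma` | training blend rate γ | 0.1 |
| `responsiveness` | simulation rate r_i band | [0.6,0.7] / [0.7,0.8] |
| `distraction_spike_prob` | spike probability/step | 0.10 / 0.03 |
| `distraction_spike_range` | spike amplitude | [0.2, 0.4] |
| `transition_threshold` | natural-transition θ | 0.45 (all states) |
| `suppression_factor` | focus collapse in wandering | 0.05 |
| `enhancement_factor` | distraction boost | 1.2 |
| `dwell_limits` | episode bands (steps = s) | MW 25±5 / 10±2; others 10±3 |
| `omega_base` | weight scale ω | 1.0 |
| `network_gain_tau` | network/bias gain τ | 1.0 |

All are overridable through `make_profile(level, overrides = ...)`, and
θ = 0.45 is uniform across target states for want of any evidence to
differentiate them.

## What the generator emulates — and what it does not

A 200-step seeded run emulates a short meditation sitting under the two
expertise parameterizations: focus decay into wandering, spontaneous
distraction spikes, detection and redirection, and the resulting dwell-time
and awareness contrasts. With the default conditions, 20-seed training
ensembles reproduce the target contrasts (novice mean wandering episode
≈ 23 steps vs expert ≈ 9; expert mean μ above novice; expert breath-focus
activation during breath control ≈ 0.7).

What passing these checks does *not* show: the traces are not fitted to any
individual's physiology or behavior; there is no sensory input, fatigue, or
circadian structure; the μ branches are piecewise constants with noise, not
a learned monitoring process; and the Granger pipeline sees short, clipped,
strongly autocorrelated series, so extracted edges describe the simulated
dynamics, not causal claims about meditators. Conclusions about real
populations require real data.

## Numerical and design notes

* **Determinism.** Every stochastic entry point takes a seed; one run seed
  expands into per-stage child seeds (`child_seed()`) so pipeline stages are
  individually reproducible. Identical seeds give bit-identical traces.
* **Degenerate inputs.** Zero-variance series make the Granger regressions
  singular and are reported as degenerate errors pairwise; inside the full
  pipeline such pairs carry no evidence and enter calibration with p = 1.
  Correlation rows for constant series are zeroed with a warning.
* **Clipping.** Activations and targets are clipped to [0, 1] after every
  update; learned weights to [0, 1.1ω]. Zero noise is permitted (for
  diagnostics and exact closed-form checks) even though the study
  conditions use positive noise.
* **Tie-breaking.** All argmax operations (dominance, natural-transition
  candidates) resolve ties by canonical order, so traces are reproducible
  across platforms.
* **End of trace.** A transition recorded at step t takes effect at t + 1;
  none is initiated at the final step, keeping transition counts equal to
  observed state changes. The trailing, right-censored episode counts as
  complete by default (`drop_censored` excludes it) — at 200 steps this
  biases novice wandering means slightly downward, which the reported
  ensemble means absorb.
* **Coverage.** In 200 simulated steps a single run visits all four states
  in roughly 60–70% of seeds (entry into `redirect_breath` hinges on
  sparsely-estimated learned T rows); ensembles cover all states. Longer
  horizons recover per-run coverage.

## Problem sizes

The shipped tests and the acceptance script use the model's native scales:
200-timestep runs, 20-seed ensembles for stochastic contrasts, 200
replicates for the test-size check of the Granger test, and 50 replicates
for planted-edge recovery — small enough to run anywhere, large enough that
the Monte-Carlo error bands (3 standard errors) are meaningful.

## Known limitations

Discrete one-second timesteps (no continuous-time integration); two fixed
expertise bundles rather than individual variation; pairwise (not
conditional) Granger inference, so mediated influences can appear as direct
edges; and the appendix-level mechanics of the original formulation
(distraction growth, feedback interactions) are represented by the stated
spike model rather than reconstructed equations.
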