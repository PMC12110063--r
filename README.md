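# vipassim

Agent-based simulation of attentional dynamics in focused-attention
(Vipassana-style) meditation.

## The problem and the model

During focused-attention meditation, practice alternates between sustained
breath focus, episodes of mind-wandering, the moment of noticing the lapse,
and redirection back to the breath. `vipassim` models this cycle as a
three-level dynamical system in which the four **meditation states**
(`breath_control`, `mind_wandering`, `meta_awareness`, `redirect_breath`)
are not scripted but *emerge* from competition among five **thoughtseeds** —
attentional agents named `breath_focus`, `equanimity`, `pain_discomfort`,
`pending_tasks` and `self_reflection` — under the regulation of a scalar
**meta-awareness** level μ.

The core machinery, for activations α ∈ [0,1]⁵ and one-second timesteps:

- **Attractor landscapes.** A state × thoughtseed weight matrix W assigns
  each state's primary attractors weights in ω·[0.9, 1.1], secondary
  attractors ω·[0.7, 0.9], and all others ω·[0.05, 0.2].
- **Training dynamics.** α(t+1) = (1−γ)·α(t) + γ·α_target + Δα_dist + η,
  with γ = 0.1, spontaneous distraction spikes Δα_dist, and bounded noise η
  (sd 0.08 for novices, 0.04 for experts). During low-awareness
  mind-wandering the breath-focus target is suppressed (×0.05) and
  distraction targets enhanced (×1.2).
- **Meta-awareness regulation.** μ follows a five-branch state-dependent
  rule with floor 0.55 (distracted wandering) and caps 0.75 / 0.85 / 0.9 in
  breath control, redirection, and meta-awareness.
- **Transitions.** Natural transitions fire when another state's attractor
  support φ (mean activation over its attractor thoughtseeds) exceeds the
  threshold θ = 0.45 *and* dominates the current state's support, after a
  minimum dwell; forced transitions fire when a per-episode dwell cap
  (drawn from each state's mean ± 2 SD band) is reached. Observed
  transitions are counted into a row-stochastic matrix T.
- **Network extraction.** Signed thoughtseed interactions are recovered
  from traces by pairwise lagged Granger causality (L = 5, likelihood-ratio
  χ² test), calibrated to (−0.7, 0.7) with strength inversely related to p,
  blended as W = 0.7·causal + 0.3·correlation, thresholded at |W| > 0.15
  and scaled into (−0.6, 0.6).
- **Simulation.** The trained model runs with momentum updates
  α_i(t+1) = r_i·Target_i + (1−r_i)·α_i, responsiveness r_i drawn from
  0.6–0.7 (novice) or 0.7–0.8 (expert), Wilson–Cowan-style targets coupling
  the interaction network, state biases and μ, winner-takes-all dominance,
  and hybrid natural/forced transitions driven by the learned T.

## Worked example

```r
library(vipassim)

profile <- make_profile("expert")
model   <- train(profile, n_steps = 200, seed = 1)
model
#> <learned_model: expert, 200 timesteps, seed 1>
#> <transition_model> 23 transitions (8 natural, 15 forced)
#> row-stochastic T (NA = state never exited):
#>                 breath_control mind_wandering meta_awareness redirect_breath
#> breath_control           0.000          0.273          0.545           0.182
#> mind_wandering           1.000          0.000          0.000           0.000
#> meta_awareness           0.833          0.000          0.000           0.167
#> redirect_breath          1.000          0.000          0.000           0.000

net <- extract_network(model$trace)
sim <- run_simulation(model, net, n_steps = 200, seed = 2)

novice <- lapply(1:20, function(s) train(make_profile("novice"), 200, seed = s)$trace)
expert <- lapply(1:20, function(s) train(make_profile("expert"), 200, seed = s)$trace)
contrast_report(novice, expert)
#> <contrast_report>
#>   traces: 20 novice, 20 expert
#>   mean meta-awareness : novice 0.653, expert 0.707
#>   mind_wandering mean episode: novice 23.2, expert 9.3 steps
#>   breath_focus in breath_control: novice 0.680, expert 0.703
```

The learned transition matrix shows the emergent cycle (wandering is exited
toward recovery states, redirection returns to breath control). The
contrast report shows the expertise signature the model is built around:
novices wander for 20–30 s with lower meta-awareness, experts recover
within ~8–12 s, hold higher awareness, and keep breath focus high while in
breath control.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/vipassim full-run --level expert --seed 7 --out-dir out/
```

writes `trace.csv`, `weights.json`, `transition_matrix.json`,
`network.json`, `sim_trace.csv`, `transitions.json` and `report.json`, each
embedding the seed and config hash for exact reruns.

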