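#' Winner-takes-all dominant thoughtseed
#'
#' @param alpha Named activation vector over the five thoughtseeds.
#' @return Name of the thoughtseed with the highest activation; exact ties
#'   go to the earlier thoughtseed in canonical order (breath_focus first).
#' @export
#' @examples
#' dominant_thoughtseed(c(breath_focus = 0.9, equanimity = 0.1,
#'   pain_discomfort = 0.1, pending_tasks = 0.1, self_reflection = 0.1))
dominant_thoughtseed <- function(alpha) {
  alpha <- alpha[thoughtseeds()]
  names(alpha)[which.max(alpha)]
}

## State-specific bias table gamma_{i,s}: +0.1 on a state's attractor
## thoughtseeds, 0 otherwise.
state_bias_table <- function(attractor_spec, bias = 0.1) {
  states <- meditation_states()
  ts <- thoughtseeds()
  B <- matrix(0, length(states), length(ts), dimnames = list(states, ts))
  for (s in states) {
    sup <- c(attractor_spec[[s]]$primary,
             attractor_spec[[s]]$secondary %||% character(0))
    B[s, sup] <- bias
  }
  B
}

#' Network-coupled activation target (simulation phase)
#'
#' Wilson-Cowan-style competitive target for every thoughtseed i:
#' `Target_i = W[state, i] + (sum_j W_net[j, i] * alpha_j) * tau
#'  + bias[state, i] * tau + mu * beta_i`, clipped to \[0, 1\].
#' `W_net[j, i]` is the signed interaction weight from source j to target i,
#' so facilitatory edges raise and inhibitory edges lower the target; the
#' state bias nudges a state's own attractor thoughtseeds upward, and
#' meta-awareness couples in through the per-thoughtseed beta.
#'
#' @param alpha Named activation vector.
#' @param state Current meditation state.
#' @param mu Meta-awareness in \[0, 1\].
#' @param weight_matrix A `state_weight_matrix` (typically the trained one).
#' @param interactions An `interaction_matrix` (or a bare 5x5 matrix,
#'   rows = source, cols = target).
#' @param profile An `expertise_profile` (supplies tau and beta).
#' @return Named per-thoughtseed target vector in \[0, 1\].
#' @export
compute_target <- function(alpha, state, mu, weight_matrix, interactions,
                           profile) {
  stopifnot(all(is.finite(alpha)), is.finite(mu))
  Wnet <- if (inherits(interactions, "interaction_matrix"))
    interactions$weights else interactions
  spec <- attr(weight_matrix, "attractor_spec")
  bias <- state_bias_table(spec)
  tau <- profile$network_gain_tau
  net_in <- as.vector(alpha[thoughtseeds()] %*% Wnet[thoughtseeds(), thoughtseeds()])
  clip(unclass(weight_matrix)[state, ] + net_in * tau +
         bias[state, ] * tau + mu * profile$meta_coupling_beta)
}

#' Momentum activation update (simulation phase)
#'
#' `alpha_i' = r_i * target_i + (1 - r_i) * alpha_i`: each thoughtseed moves
#' toward its target at its own responsiveness rate, so with a fixed target
#' the gap contracts by exactly `(1 - r_i)` per step.
#'
#' @param alpha Current activations.
#' @param target Target activations (see [compute_target()]).
#' @param r Per-thoughtseed responsiveness in (0, 1) (scalar or vector).
#' @return Next activation vector.
#' @export
step_activation <- function(alpha, target, r) {
  stopifnot(all(r > 0), all(r <= 1))
  r * target + (1 - r) * alpha
}

#' One state-transition decision of the simulation loop
#'
#' Hybrid rule: a natural (threshold-crossing) transition fires when another
#' state's attractor support dominates (see [natural_transition_check()]);
#' otherwise, when the episode's dwell cap is reached, a forced transition
#' samples the next state from the learned transition-matrix row
#' (renormalized off-diagonal), falling back to the empirical reference row
#' for states never exited during training; otherwise the state is kept.
#'
#' @param state Current meditation state.
#' @param alpha Named activation vector.
#' @param dwell Timesteps spent in `state` (>= 1).
#' @param model A `learned_model` from [train()].
#' @param profile An `expertise_profile`.
#' @param dwell_cap Dwell limit in force for this episode (defaults to the
#'   state's hard cap).
#' @param reference Reference matrix used as fallback; defaults to the
#'   profile level's packaged matrix.
#' @return List with `state` (next state) and `kind`
#'   (`"natural"`, `"forced"` or `"none"`).
#' @export
transition_step <- function(state, alpha, dwell, model, profile,
                            dwell_cap = profile$dwell_limits[[state]]["max"],
                            reference = reference_transition_matrix(profile$level)) {
  stopifnot(dwell >= 1)
  nxt <- natural_transition_check(state, alpha, dwell, model$weight_matrix,
                                  profile)
  if (!is.null(nxt)) return(list(state = nxt, kind = "natural"))
  if (dwell >= dwell_cap) {
    row <- model$transition_model$T[state, ]
    if (any(is.na(row)) || sum(row[setdiff(names(row), state)]) <= 0)
      row <- reference$matrix[state, ]
    return(list(state = sample_forced_target(state, row), kind = "forced"))
  }
  list(state = state, kind = "none")
}

#' Simulate the trained model
#'
#' Runs the hierarchical simulation for `n_steps` timesteps: network-coupled
#' targets ([compute_target()]), momentum updates at per-thoughtseed
#' responsiveness drawn once per run from the profile's range
#' ([step_activation()]), distraction spikes and activation noise as in
#' training, winner-takes-all dominance, meta-awareness regulation, and
#' hybrid natural/forced state transitions driven by the learned transition
#' matrix ([transition_step()]). Starts in breath_control with activations
#' set to the clipped trained breath_control weight row.
#'
#' @param model A `learned_model` from [train()].
#' @param interactions An `interaction_matrix` from [extract_network()].
#' @param profile An `expertise_profile`; defaults to the model's.
#' @param n_steps Number of timesteps (>= 1), default 200.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   traces.
#' @return A `meditation_trace` data frame (same schema as [train()]'s
#'   trace) with attributes `transitions` (data frame of t, from, to, kind),
#'   `responsiveness` (the sampled r_i), `level` and `seed`.
#' @export
#' @examples
#' m <- train(make_profile("expert"), n_steps = 120, seed = 1)
#' net <- extract_network(m$trace)
#' tr <- run_simulation(m, net, n_steps = 100, seed = 2)
#' table(tr$state)
run_simulation <- function(model, interactions, profile = model$profile,
                           n_steps = 200, seed = NULL) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop_vipassim("n_steps must be >= 1", class = "vipassim_validation_error")
  n_steps <- as.integer(n_steps)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(model, "learned_model"))

  ts <- thoughtseeds()
  W <- model$weight_matrix
  reference <- reference_transition_matrix(profile$level)
  r <- stats::setNames(
    stats::runif(length(ts), profile$responsiveness[1],
                 profile$responsiveness[2]), ts)

  state <- "breath_control"
  alpha <- clip(unclass(W)[state, ])
  dominant <- dominant_thoughtseed(alpha)
  mu <- meta_awareness_update(state, dominant, profile)
  dwell <- 1L
  cap <- sample_dwell_cap(state, profile)

  trace <- empty_trace(n_steps)
  transitions <- list()

  for (t in seq_len(n_steps)) {
    target <- compute_target(alpha, state, mu, W, interactions, profile)
    delta <- distraction_growth(alpha, profile)
    n <- length(alpha)
    eta <- switch(profile$noise_law,
      gaussian = stats::rnorm(n, 0, profile$noise_scale),
      uniform = stats::runif(n, -profile$noise_scale, profile$noise_scale))
    alpha <- clip(step_activation(alpha, target, r) + delta + eta)
    dominant <- dominant_thoughtseed(alpha)
    mu <- meta_awareness_update(state, dominant, profile)

    kind <- "none"
    if (t < n_steps) {
      step <- transition_step(state, alpha, dwell, model, profile, cap,
                              reference)
      kind <- step$kind
    } else {
      step <- list(state = state, kind = "none")
    }

    trace$t[t] <- t
    trace$state[t] <- state
    trace$dominant[t] <- dominant
    trace$mu[t] <- mu
    for (i in ts) trace[[paste0("alpha_", i)]][t] <- alpha[[i]]
    trace$transition_kind[t] <- kind

    if (kind != "none") {
      transitions[[length(transitions) + 1L]] <-
        data.frame(t = t, from = state, to = step$state, kind = kind,
                   stringsAsFactors = FALSE)
      state <- step$state
      dwell <- 1L
      cap <- sample_dwell_cap(state, profile)
    } else {
      dwell <- dwell + 1L
    }
  }

  out <- new_trace(trace, transitions, profile$level, seed)
  attr(out, "responsiveness") <- r
  out
}
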