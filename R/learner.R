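#' Initialize the state-weight matrix
#'
#' Builds the 4x5 state x thoughtseed weight matrix W defining one attractor
#' landscape per meditation state. Each entry is drawn uniformly from a band
#' scaled by `omega_base`: \[0.9, 1.1\] for a state's primary attractors,
#' \[0.7, 0.9\] for secondary attractors, \[0.05, 0.2\] otherwise. Draws use
#' R's current RNG stream; call `set.seed()` (or let [train()] do it) for
#' reproducibility.
#'
#' @param attractor_spec Per-state attractor lists, see
#'   [default_attractor_spec()].
#' @param omega_base Overall weight scale (default 1).
#' @return A `state_weight_matrix`: a numeric matrix with states as rows and
#'   thoughtseeds as columns, carrying the attractor spec and `omega_base`
#'   as attributes.
#' @export
#' @examples
#' set.seed(1)
#' W <- init_weight_matrix(default_attractor_spec())
#' W["breath_control", "breath_focus"]  # in [0.9, 1.1]
init_weight_matrix <- function(attractor_spec = default_attractor_spec(),
                               omega_base = 1.0) {
  validate_attractor_spec(attractor_spec)
  stopifnot(is.numeric(omega_base), length(omega_base) == 1L, omega_base >= 0)
  states <- meditation_states()
  ts <- thoughtseeds()
  W <- matrix(NA_real_, length(states), length(ts),
              dimnames = list(states, ts))
  for (s in states) {
    pri <- attractor_spec[[s]]$primary
    sec <- attractor_spec[[s]]$secondary %||% character(0)
    for (i in ts) {
      band <-
        if (i %in% pri) c(0.9, 1.1)
        else if (i %in% sec) c(0.7, 0.9)
        else c(0.05, 0.2)
      W[s, i] <- omega_base * stats::runif(1, band[1], band[2])
    }
  }
  new_state_weight_matrix(W, attractor_spec, omega_base)
}

new_state_weight_matrix <- function(W, attractor_spec, omega_base) {
  structure(W, attractor_spec = attractor_spec, omega_base = omega_base,
            class = c("state_weight_matrix", "matrix", "array"))
}

#' @export
print.state_weight_matrix <- function(x, ...) {
  cat(sprintf("<state_weight_matrix> (omega_base = %g)\n",
              attr(x, "omega_base")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Spontaneous distraction spikes
#'
#' Each distraction thoughtseed independently spikes with probability
#' `distraction_spike_prob`, by an amplitude drawn uniformly from
#' `distraction_spike_range`. Non-distraction thoughtseeds never spike.
#'
#' @param alpha Current activation vector (unused by the default spike model;
#'   kept in the signature so alternative activation-dependent spike models
#'   can drop in).
#' @param profile An `expertise_profile`.
#' @return Named per-thoughtseed increment vector (zero outside distractions).
#' @export
distraction_growth <- function(alpha, profile) {
  delta <- stats::setNames(numeric(length(thoughtseeds())), thoughtseeds())
  for (d in distraction_thoughtseeds()) {
    if (stats::runif(1) < profile$distraction_spike_prob) {
      delta[d] <- stats::runif(1, profile$distraction_spike_range[1],
                               profile$distraction_spike_range[2])
    }
  }
  delta
}

#' State- and awareness-modulated activation target
#'
#' The base target is the current state's weight row clipped to \[0, 1\].
#' During mind_wandering with low meta-awareness (mu < 0.6) the breath_focus
#' target is suppressed by `suppression_factor` and the distraction targets
#' are enhanced by `enhancement_factor` (then re-clipped), modeling the
#' attentional lapse in which the focus target collapses while distractions
#' are amplified.
#'
#' @param state Current meditation state.
#' @param mu Meta-awareness in \[0, 1\].
#' @param weight_matrix A `state_weight_matrix`.
#' @param profile An `expertise_profile`.
#' @return Named per-thoughtseed target vector in \[0, 1\].
#' @export
modulated_target <- function(state, mu, weight_matrix, profile) {
  stopifnot(state %in% meditation_states(), mu >= 0, mu <= 1)
  target <- clip(unclass(weight_matrix)[state, ])
  if (state == "mind_wandering" && mu < 0.6) {
    target["breath_focus"] <- target["breath_focus"] * profile$suppression_factor
    dn <- distraction_thoughtseeds()
    target[dn] <- target[dn] * profile$enhancement_factor
    target <- clip(target)
  }
  target
}

#' One activation update step of the training dynamics
#'
#' Implements the blended update
#' `alpha' = (1 - gamma) * alpha + gamma * target + delta_dist + eta`,
#' clipped to \[0, 1\], with eta i.i.d. noise per thoughtseed (Gaussian with
#' sd `noise_scale`, or uniform on +/- `noise_scale` when
#' `profile$noise_law == "uniform"`).
#'
#' @param alpha Current activations in \[0, 1\].
#' @param target Target activations (see [modulated_target()]).
#' @param delta_dist Distraction increment (see [distraction_growth()]).
#' @param profile An `expertise_profile`.
#' @return Next activation vector, clipped to \[0, 1\].
#' @export
update_activations <- function(alpha, target, delta_dist, profile) {
  stopifnot(all(is.finite(alpha)), all(is.finite(target)))
  g <- profile$momentum_gamma
  n <- length(alpha)
  eta <- switch(profile$noise_law,
    gaussian = stats::rnorm(n, 0, profile$noise_scale),
    uniform = stats::runif(n, -profile$noise_scale, profile$noise_scale))
  clip((1 - g) * alpha + g * target + delta_dist + eta)
}

#' State-dependent meta-awareness regulation
#'
#' Meta-awareness mu is set each step from the current state and dominant
#' thoughtseed, with noise eps ~ N(0, meta_noise_scale^2):
#' \itemize{
#'   \item mind_wandering, dominant in distractions: `max(0.55, 0.55 + eps)`
#'     (awareness collapses to its floor while distracted);
#'   \item mind_wandering otherwise: `max(0.55, 1.0 + eps)` (detection:
#'     a non-distraction winning during wandering pulls awareness up);
#'   \item redirect_breath: `min(0.85, 0.85 + eps)`;
#'   \item breath_control: `min(0.75, 0.8 + eps)`;
#'   \item meta_awareness: `min(0.9, 0.9 + eps)`.
#' }
#' The result is clipped to \[0, 1\]; across all branches mu >= 0.55 up to
#' the clip, so every trace keeps a 0.55 awareness floor.
#'
#' @param state Current meditation state.
#' @param dominant Currently dominant thoughtseed.
#' @param profile An `expertise_profile`.
#' @return Meta-awareness scalar in \[0, 1\].
#' @export
#' @examples
#' p <- make_profile("expert", overrides = list(meta_noise_scale = 1e-12))
#' meta_awareness_update("meta_awareness", "self_reflection", p)  # 0.9
meta_awareness_update <- function(state, dominant, profile) {
  stopifnot(state %in% meditation_states())
  eps <- stats::rnorm(1, 0, profile$meta_noise_scale)
  mu <- switch(state,
    mind_wandering =
      if (dominant %in% distraction_thoughtseeds())
        max(0.55, 0.6 - 0.05 + eps)
      else
        max(0.55, 0.6 + 0.4 + eps),
    redirect_breath = min(0.85, 0.6 + 0.25 + eps),
    breath_control = min(0.75, 0.6 + 0.2 + eps),
    meta_awareness = min(0.9, 0.6 + 0.3 + eps))
  clip(mu)
}

#' Attractor support of each meditation state
#'
#' phi_s(alpha): the mean activation over state s's primary and secondary
#' attractor thoughtseeds — how strongly the current activation pattern
#' supports each state's basin.
#'
#' @param alpha Named activation vector.
#' @param attractor_spec Per-state attractor lists.
#' @return Named numeric vector over meditation states.
#' @export
attractor_support <- function(alpha, attractor_spec = default_attractor_spec()) {
  vapply(meditation_states(), function(s) {
    sup <- c(attractor_spec[[s]]$primary,
             attractor_spec[[s]]$secondary %||% character(0))
    mean(alpha[sup])
  }, numeric(1))
}

#' Natural (threshold-crossing) transition check
#'
#' A natural transition to another state j is permitted when (i) the dwell
#' time has reached the current state's dwell minimum, (ii) j's attractor
#' support phi_j(alpha) exceeds the transition threshold theta_j, and (iii)
#' phi_j strictly exceeds the current state's own support phi_current — a
#' basin only captures the trajectory when its attractor evidence dominates
#' the basin the system is in (in particular, a state whose attractor set
#' ties the current one, as redirect_breath ties breath_control, never
#' captures by threshold alone). Among permitted candidates the one with the
#' largest phi wins; exact ties go to the earlier state in canonical order.
#'
#' @param state Current meditation state.
#' @param alpha Named activation vector.
#' @param dwell Timesteps already spent in `state` (>= 1).
#' @param weight_matrix A `state_weight_matrix` (supplies the attractor spec).
#' @param profile An `expertise_profile`.
#' @return Candidate next-state name, or `NULL` if no transition is permitted.
#' @export
natural_transition_check <- function(state, alpha, dwell, weight_matrix,
                                     profile) {
  stopifnot(dwell >= 1)
  if (dwell < profile$dwell_limits[[state]]["min"]) return(NULL)
  spec <- attr(weight_matrix, "attractor_spec")
  phi <- attractor_support(alpha, spec)
  others <- setdiff(meditation_states(), state)
  ok <- others[phi[others] > profile$transition_threshold[others] &
                 phi[others] > phi[state]]
  if (!length(ok)) return(NULL)
  ok[which.max(phi[ok])]
}

## Sample a next state != `state` from a transition-matrix row, renormalized
## over its off-diagonal entries.
sample_forced_target <- function(state, row) {
  others <- setdiff(names(row), state)
  w <- row[others]
  if (sum(w) <= 0)
    stop_vipassim("transition row out of state '%s' has no off-diagonal mass",
                  state, class = "vipassim_validation_error")
  sample(others, 1, prob = w / sum(w))
}

#' Forced (dwell-limit) transition
#'
#' When a state's dwell limit is reached without a natural transition, the
#' next state is sampled from the reference-matrix row of the current state,
#' renormalized over its off-diagonal entries (the system must leave).
#'
#' @param state Current meditation state.
#' @param dwell Timesteps spent in `state`; must have reached `dwell_cap`.
#' @param profile An `expertise_profile`.
#' @param reference A `reference_transition_matrix` for the profile's level.
#' @param dwell_cap The dwell limit in force for this episode; defaults to
#'   the state's hard cap `dwell_limits[state]["max"]`. [train()] and
#'   [run_simulation()] draw a per-episode cap from N(mean, sd) clipped to
#'   \[min, max\].
#' @return Next state name (always different from `state`).
#' @export
forced_transition <- function(state, dwell, profile, reference,
                              dwell_cap = profile$dwell_limits[[state]]["max"]) {
  if (dwell < dwell_cap)
    stop_vipassim(
      "forced_transition called with dwell %d below the dwell cap %g",
      dwell, dwell_cap, class = "vipassim_contract_error")
  sample_forced_target(state, reference$matrix[state, ])
}

## Per-episode dwell cap: N(mean, sd) rounded, clipped to [min, max].
sample_dwell_cap <- function(state, profile) {
  d <- profile$dwell_limits[[state]]
  clip(round(stats::rnorm(1, d["mean"], d["sd"])), d["min"], d["max"])
}

empty_trace <- function(n) {
  ts <- thoughtseeds()
  tr <- data.frame(
    t = integer(n), state = character(n), dominant = character(n),
    mu = numeric(n), stringsAsFactors = FALSE)
  for (i in ts) tr[[paste0("alpha_", i)]] <- numeric(n)
  tr$transition_kind <- character(n)
  tr
}

#' Train the meditation model
#'
#' Runs the rule-based training loop for `n_steps` timesteps (default 200,
#' one timestep = 1 s): at each step the state- and awareness-modulated
#' target is computed, distraction spikes and noise are applied through the
#' blended activation update, the dominant thoughtseed is selected
#' (winner-takes-all), meta-awareness is re-regulated, the current state's
#' weight row is nudged toward the observed activations by the 90/10
#' momentum rule (clipped to \[0, 1.1 * omega_base\]), and a natural or
#' forced state transition is applied. Every transition is counted into a
#' row-stochastic transition matrix, and the activation vector at each
#' transition is averaged per (from, to) pair.
#'
#' The run starts in breath_control with activations set to the clipped
#' breath_control weight row. A transition recorded at step t takes effect
#' at step t + 1; no transition is initiated at the final step, so
#' transition counts always equal the number of state changes in the trace.
#'
#' @param profile An `expertise_profile`.
#' @param attractor_spec Per-state attractor lists.
#' @param n_steps Number of timesteps (>= 1), default 200.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   models.
#' @return A `learned_model`: list with `weight_matrix`, `transition_model`,
#'   `trace` (one row per timestep: t, state, dominant, mu, the five
#'   activations, transition_kind), `profile`, `attractor_spec`, `seed`.
#' @export
#' @examples
#' m <- train(make_profile("expert"), n_steps = 50, seed = 1)
#' table(m$trace$state)
train <- function(profile, attractor_spec = default_attractor_spec(),
                  n_steps = 200, seed = NULL) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop_vipassim("n_steps must be >= 1", class = "vipassim_validation_error")
  n_steps <- as.integer(n_steps)
  if (!is.null(seed)) set.seed(seed)
  validate_attractor_spec(attractor_spec)

  states <- meditation_states()
  ts <- thoughtseeds()
  reference <- reference_transition_matrix(profile$level)
  W <- init_weight_matrix(attractor_spec, profile$omega_base)
  wcap <- 1.1 * profile$omega_base

  state <- "breath_control"
  alpha <- clip(unclass(W)[state, ])
  dominant <- dominant_thoughtseed(alpha)
  mu <- meta_awareness_update(state, dominant, profile)
  dwell <- 1L
  cap <- sample_dwell_cap(state, profile)

  counts <- matrix(0L, 4, 4, dimnames = list(states, states))
  tr_alpha_sum <- list()
  n_forced <- 0L
  n_natural <- 0L
  transitions <- list()
  trace <- empty_trace(n_steps)

  for (t in seq_len(n_steps)) {
    target <- modulated_target(state, mu, W, profile)
    delta <- distraction_growth(alpha, profile)
    alpha <- update_activations(alpha, target, delta, profile)
    dominant <- dominant_thoughtseed(alpha)
    mu <- meta_awareness_update(state, dominant, profile)
    W[state, ] <- clip(0.9 * unclass(W)[state, ] + 0.1 * alpha, 0, wcap)

    kind <- "none"
    nxt <- NULL
    if (t < n_steps) {
      nxt <- natural_transition_check(state, alpha, dwell, W, profile)
      if (!is.null(nxt)) {
        kind <- "natural"
      } else if (dwell >= cap) {
        nxt <- forced_transition(state, dwell, profile, reference, cap)
        kind <- "forced"
      }
    }

    trace$t[t] <- t
    trace$state[t] <- state
    trace$dominant[t] <- dominant
    trace$mu[t] <- mu
    for (i in ts) trace[[paste0("alpha_", i)]][t] <- alpha[[i]]
    trace$transition_kind[t] <- kind

    if (!is.null(nxt)) {
      counts[state, nxt] <- counts[state, nxt] + 1L
      key <- paste0(state, "->", nxt)
      tr_alpha_sum[[key]] <- (tr_alpha_sum[[key]] %||% numeric(length(ts))) + alpha
      if (kind == "forced") n_forced <- n_forced + 1L else n_natural <- n_natural + 1L
      transitions[[length(transitions) + 1L]] <-
        data.frame(t = t, from = state, to = nxt, kind = kind,
                   stringsAsFactors = FALSE)
      state <- nxt
      dwell <- 1L
      cap <- sample_dwell_cap(state, profile)
    } else {
      dwell <- dwell + 1L
    }
  }

  tmodel <- new_transition_model(counts, tr_alpha_sum, n_forced, n_natural,
                                 transitions)
  structure(
    list(weight_matrix = W, transition_model = tmodel,
         trace = new_trace(trace, transitions, profile$level, seed),
         profile = profile, attractor_spec = attractor_spec, seed = seed),
    class = "learned_model")
}

new_transition_model <- function(counts, tr_alpha_sum, n_forced, n_natural,
                                 transitions) {
  Tm <- counts / ifelse(rowSums(counts) > 0, rowSums(counts), 1)
  Tm[rowSums(counts) == 0, ] <- NA_real_
  mean_alpha <- lapply(names(tr_alpha_sum), function(key) {
    ft <- strsplit(key, "->", fixed = TRUE)[[1]]
    tr_alpha_sum[[key]] / counts[ft[1], ft[2]]
  })
  names(mean_alpha) <- names(tr_alpha_sum)
  mean_alpha <- lapply(mean_alpha, stats::setNames, thoughtseeds())
  structure(
    list(counts = counts, T = Tm, mean_transition_alpha = mean_alpha,
         n_forced = n_forced, n_natural = n_natural,
         transitions = if (length(transitions))
           do.call(rbind, transitions) else
           data.frame(t = integer(0), from = character(0), to = character(0),
                      kind = character(0), stringsAsFactors = FALSE)),
    class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d transitions (%d natural, %d forced)\n",
              sum(x$counts), x$n_natural, x$n_forced))
  cat("row-stochastic T (NA = state never exited):\n")
  print(round(x$T, 3))
  invisible(x)
}

#' @export
print.learned_model <- function(x, ...) {
  cat(sprintf("<learned_model: %s, %d timesteps, seed %s>\n",
              x$profile$level, nrow(x$trace),
              x$seed %||% "unset"))
  print(x$transition_model)
  invisible(x)
}

new_trace <- function(df, transitions, level, seed) {
  attr(df, "transitions") <- if (length(transitions))
    do.call(rbind, transitions) else NULL
  attr(df, "level") <- level
  attr(df, "seed") <- seed
  class(df) <- c("meditation_trace", "data.frame")
  df
}

#' @export
print.meditation_trace <- function(x, ...) {
  cat(sprintf("<meditation_trace> %d timesteps (%s)\n", nrow(x),
              attr(x, "level") %||% "level unknown"))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Activation columns of a trace as a matrix
#'
#' @param trace A trace data frame as produced by [train()] or
#'   [run_simulation()].
#' @return Numeric matrix, timesteps x thoughtseeds.
#' @export
trace_activations <- function(trace) {
  cols <- paste0("alpha_", thoughtseeds())
  stopifnot(all(cols %in% names(trace)))
  m <- as.matrix(as.data.frame(trace)[, cols])
  colnames(m) <- thoughtseeds()
  m
}
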