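# Shared test fixtures, all generated in code.

# Profile with all stochastic terms switched off (deterministic dynamics).
quiet_profile <- function(level = "expert", ...) {
  make_profile(level, overrides = c(list(
    noise_scale = 0, meta_noise_scale = 0, distraction_spike_prob = 0), ...))
}

# Dwell limits that never force a transition (effectively infinite caps).
endless_dwell <- function() {
  dw <- lapply(meditation_states(), function(s)
    c(mean = 1e6, sd = 1, min = 3, max = 1e6 + 2))
  names(dw) <- meditation_states()
  dw
}

named_alpha <- function(...) {
  a <- stats::setNames(numeric(5), thoughtseeds())
  vals <- list(...)
  a[names(vals)] <- unlist(vals)
  a
}

# Ensembles used by several stochastic checks; trained once per session.
ensemble_cache <- new.env(parent = emptyenv())
training_ensemble <- function(level, n_seeds = 20, n_steps = 200) {
  key <- paste(level, n_seeds, n_steps, sep = "_")
  if (is.null(ensemble_cache[[key]])) {
    ensemble_cache[[key]] <- lapply(seq_len(n_seeds), function(s)
      train(make_profile(level), n_steps = n_steps, seed = s))
  }
  ensemble_cache[[key]]
}

pooled_mw_durations <- function(models) {
  unlist(lapply(models, function(m) {
    ep <- episode_durations(m$trace)$episodes
    ep$duration[ep$state == "mind_wandering"]
  }))
}

clipped_row <- function(W, state) pmin(pmax(unclass(W)[state, ], 0), 1)

# Deterministic weight matrix with hand-set entries for modulation tests.
new_weight_fixture <- function() {
  W <- matrix(0.1, 4, 5, dimnames = list(meditation_states(), thoughtseeds()))
  W["breath_control", "breath_focus"] <- 0.95
  W["breath_control", "equanimity"] <- 0.8
  W["mind_wandering", "breath_focus"] <- 0.8
  W["mind_wandering", "pain_discomfort"] <- 0.9
  W["mind_wandering", "pending_tasks"] <- 0.5
  W["meta_awareness", "self_reflection"] <- 1.0
  W["redirect_breath", "equanimity"] <- 0.9
  W["redirect_breath", "breath_focus"] <- 0.9
  vipassim:::new_state_weight_matrix(W, default_attractor_spec(), 1.0)
}
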