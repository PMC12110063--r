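#' Expertise profiles
#'
#' All expertise-dependent parameters of the simulator are bundled in an
#' `expertise_profile`. The two levels differ in activation-noise amplitude,
#' thoughtseed responsiveness, spontaneous-distraction rate, and
#' mind_wandering dwell limits; everything else is shared.
#'
#' Fields (units are dimensionless activations unless noted):
#' \describe{
#'   \item{level}{`"novice"` or `"expert"`.}
#'   \item{noise_scale}{sd of per-thoughtseed activation noise
#'     (novice 0.08, expert 0.04).}
#'   \item{meta_noise_scale}{sd of the meta-awareness noise term (0.03).}
#'   \item{noise_law}{`"gaussian"` (default) or `"uniform"`
#'     (uniform on +/- noise_scale).}
#'   \item{responsiveness}{two-element range from which per-thoughtseed
#'     responsiveness r_i is drawn once per simulation run
#'     (novice \[0.6, 0.7\], expert \[0.7, 0.8\]).}
#'   \item{momentum_gamma}{blending rate gamma of the activation update and
#'     the 90/10 weight-learning rule (0.1).}
#'   \item{omega_base}{overall weight scale of the state-weight matrix (1).}
#'   \item{dwell_limits}{per-state list of `c(mean, sd, min, max)` dwell
#'     targets in timesteps (1 timestep = 1 s); `max = mean + 2*sd`,
#'     `min = max(3, mean - 2*sd)`.}
#'   \item{transition_threshold}{threshold theta on attractor support for a
#'     natural transition, per target state (0.45 each).}
#'   \item{suppression_factor}{breath_focus target multiplier during
#'     low-awareness mind_wandering (0.05).}
#'   \item{enhancement_factor}{distraction target multiplier during
#'     low-awareness mind_wandering (1.2).}
#'   \item{distraction_spike_prob}{per-step probability that a distraction
#'     thoughtseed spikes spontaneously (novice 0.10, expert 0.03).}
#'   \item{distraction_spike_range}{uniform amplitude range of a spike
#'     (\[0.2, 0.4\]).}
#'   \item{meta_coupling_beta}{per-thoughtseed coupling of meta-awareness
#'     into activation targets.}
#'   \item{network_gain_tau}{gain on the interaction-network and state-bias
#'     terms of the simulator target (1).}
#' }
#'
#' @param level `"novice"` or `"expert"`.
#' @param overrides Optional named list of field overrides, applied after the
#'   level defaults and re-validated.
#' @return An object of class `expertise_profile` (a validated named list).
#' @export
#' @examples
#' make_profile("expert")$noise_scale   # 0.04
#' make_profile("novice")$noise_scale   # 0.08
make_profile <- function(level = c("novice", "expert"), overrides = list()) {
  if (!is.character(level) || length(level) != 1L ||
      !level %in% c("novice", "expert")) {
    stop_vipassim("unknown expertise level: %s",
                  paste(format(level), collapse = ", "),
                  class = "vipassim_config_error")
  }
  prof <- default_profile_fields(level)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop_vipassim("profile overrides must be a named list",
                    class = "vipassim_config_error")
    }
    unknown <- setdiff(names(overrides), names(prof))
    if (length(unknown)) {
      stop_vipassim("unknown profile field(s): %s (valid: %s)",
                    paste(unknown, collapse = ", "),
                    paste(names(prof), collapse = ", "),
                    class = "vipassim_config_error")
    }
    prof[names(overrides)] <- overrides
  }
  prof <- structure(prof, class = "expertise_profile")
  validate_profile(prof)
  prof
}

default_profile_fields <- function(level) {
  states <- meditation_states()
  ts <- thoughtseeds()
  mw <- if (level == "novice") c(mean = 25, sd = 5) else c(mean = 10, sd = 2)
  dwell <- lapply(states, function(s) {
    ms <- if (s == "mind_wandering") mw else c(mean = 10, sd = 3)
    c(mean = unname(ms["mean"]), sd = unname(ms["sd"]),
      min = max(3, unname(ms["mean"]) - 2 * unname(ms["sd"])),
      max = unname(ms["mean"]) + 2 * unname(ms["sd"]))
  })
  names(dwell) <- states
  beta <- c(breath_focus = 0.1, equanimity = 0.3, pain_discomfort = -0.2,
            pending_tasks = -0.2, self_reflection = 0.3)[ts]
  list(
    level = level,
    noise_scale = if (level == "novice") 0.08 else 0.04,
    meta_noise_scale = 0.03,
    noise_law = "gaussian",
    responsiveness = if (level == "novice") c(0.6, 0.7) else c(0.7, 0.8),
    momentum_gamma = 0.1,
    omega_base = 1.0,
    dwell_limits = dwell,
    transition_threshold = stats::setNames(rep(0.45, 4), states),
    suppression_factor = 0.05,
    enhancement_factor = 1.2,
    distraction_spike_prob = if (level == "novice") 0.10 else 0.03,
    distraction_spike_range = c(0.2, 0.4),
    meta_coupling_beta = beta,
    network_gain_tau = 1.0
  )
}

validate_profile <- function(p) {
  fail <- function(field, why) {
    stop_vipassim("invalid profile field '%s': %s", field, why,
                  class = "vipassim_validation_error")
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  ## zero noise is allowed for deterministic diagnostics; defaults are > 0
  if (!num1(p$noise_scale) || p$noise_scale < 0)
    fail("noise_scale", "must be a nonnegative number")
  if (!num1(p$meta_noise_scale) || p$meta_noise_scale < 0)
    fail("meta_noise_scale", "must be a nonnegative number")
  if (!p$noise_law %in% c("gaussian", "uniform"))
    fail("noise_law", "must be 'gaussian' or 'uniform'")
  if (!num1(p$momentum_gamma) || p$momentum_gamma <= 0 || p$momentum_gamma >= 1)
    fail("momentum_gamma", "must lie in (0, 1)")
  r <- p$responsiveness
  if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
      r[1] > r[2] || r[1] <= 0 || r[2] >= 1)
    fail("responsiveness", "must be an increasing range inside (0, 1)")
  if (!num1(p$omega_base) || p$omega_base < 0)
    fail("omega_base", "must be a nonnegative number")
  if (!is.list(p$dwell_limits) ||
      !setequal(names(p$dwell_limits), meditation_states()))
    fail("dwell_limits", "must be a list with one entry per meditation state")
  for (s in meditation_states()) {
    d <- p$dwell_limits[[s]]
    if (!is.numeric(d) || !all(c("mean", "sd", "min", "max") %in% names(d)))
      fail("dwell_limits", sprintf("entry '%s' needs mean, sd, min, max", s))
    if (!(d["min"] > 0 && d["min"] <= d["mean"] && d["mean"] <= d["max"]))
      fail("dwell_limits", sprintf("entry '%s' needs 0 < min <= mean <= max", s))
  }
  th <- p$transition_threshold
  if (!is.numeric(th) || !setequal(names(th), meditation_states()) ||
      any(!is.finite(th)))
    fail("transition_threshold", "must be a named numeric per meditation state")
  if (!num1(p$suppression_factor) || p$suppression_factor >= 1 ||
      p$suppression_factor < 0)
    fail("suppression_factor", "must lie in [0, 1)")
  if (!num1(p$enhancement_factor) || p$enhancement_factor <= 1)
    fail("enhancement_factor", "must exceed 1")
  if (!num1(p$distraction_spike_prob) || p$distraction_spike_prob < 0 ||
      p$distraction_spike_prob > 1)
    fail("distraction_spike_prob", "must lie in [0, 1]")
  sr <- p$distraction_spike_range
  if (!is.numeric(sr) || length(sr) != 2L || sr[1] > sr[2] || any(sr < 0))
    fail("distraction_spike_range", "must be a nondecreasing nonnegative range")
  b <- p$meta_coupling_beta
  if (!is.numeric(b) || !setequal(names(b), thoughtseeds()) || any(!is.finite(b)))
    fail("meta_coupling_beta", "must be a named numeric per thoughtseed")
  if (!num1(p$network_gain_tau))
    fail("network_gain_tau", "must be a finite number")
  invisible(p)
}

#' @export
print.expertise_profile <- function(x, ...) {
  cat(sprintf("<expertise_profile: %s>\n", x$level))
  cat(sprintf("  activation noise sd : %.3f (%s)\n", x$noise_scale, x$noise_law))
  cat(sprintf("  responsiveness range: [%.2f, %.2f]\n",
              x$responsiveness[1], x$responsiveness[2]))
  cat(sprintf("  spike prob / range  : %.2f / [%.2f, %.2f]\n",
              x$distraction_spike_prob, x$distraction_spike_range[1],
              x$distraction_spike_range[2]))
  dw <- vapply(x$dwell_limits, function(d)
    sprintf("%g+/-%g [%g,%g]", d["mean"], d["sd"], d["min"], d["max"]), "")
  cat("  dwell (mean+/-sd [min,max]):\n")
  for (s in names(dw)) cat(sprintf("    %-16s %s\n", s, dw[[s]]))
  invisible(x)
}

## Printed entries of the empirical reference transition matrices.
## Everything not listed here is mass-filled (see fill rule below) and
## flagged "filled" in the provenance matrix.
printed_reference_entries <- function(level) {
  if (level == "expert") {
    list(
      breath_control = c(breath_control = 0.55, meta_awareness = 0.25),
      mind_wandering = c(mind_wandering = 0.50, meta_awareness = 0.25),
      meta_awareness = c(redirect_breath = 0.80),
      redirect_breath = c(breath_control = 0.90)
    )
  } else {
    list(
      breath_control = c(breath_control = 0.50, mind_wandering = 0.35),
      mind_wandering = c(mind_wandering = 0.70),
      meta_awareness = c(redirect_breath = 0.65),
      redirect_breath = c(breath_control = 0.70, mind_wandering = 0.20)
    )
  }
}

#' Empirical reference state-transition matrix
#'
#' Returns the packaged 4x4 row-stochastic reference matrix of empirical
#' state-transition probabilities for one expertise level. Entries reported
#' in the empirical meditation literature are stored verbatim and flagged
#' `"printed"`; the literature does not report full rows, so the remaining
#' probability mass of each row is split equally over the unreported entries,
#' which are flagged `"filled"`. Analyses should only rely on `printed`
#' entries; `filled` entries exist to make each row a proper distribution.
#'
#' @param level `"novice"` or `"expert"`.
#' @return An object of class `reference_transition_matrix`: a list with
#'   `level`, `matrix` (4x4, rows sum to 1) and `provenance` (character
#'   matrix, `"printed"` or `"filled"`).
#' @export
#' @examples
#' ref <- reference_transition_matrix("expert")
#' ref$matrix["meta_awareness", "redirect_breath"]  # 0.80
reference_transition_matrix <- function(level = c("novice", "expert")) {
  level <- match.arg(level)
  states <- meditation_states()
  m <- matrix(NA_real_, 4, 4, dimnames = list(states, states))
  prov <- matrix("filled", 4, 4, dimnames = list(states, states))
  printed <- printed_reference_entries(level)
  for (from in states) {
    row <- printed[[from]]
    m[from, names(row)] <- row
    prov[from, names(row)] <- "printed"
    open <- setdiff(states, names(row))
    m[from, open] <- (1 - sum(row)) / length(open)
  }
  structure(list(level = level, matrix = m, provenance = prov),
            class = "reference_transition_matrix")
}

#' @export
print.reference_transition_matrix <- function(x, ...) {
  cat(sprintf("<reference_transition_matrix: %s>\n", x$level))
  print(round(x$matrix, 4))
  cat(sprintf("  (%d printed entries, %d filled)\n",
              sum(x$provenance == "printed"), sum(x$provenance == "filled")))
  invisible(x)
}

#' Default attractor assignment of thoughtseeds to meditation states
#'
#' Each meditation state is an attractor basin supported by specific
#' thoughtseeds: breath_control by breath_focus (with equanimity as
#' secondary support), mind_wandering by the two distractions,
#' meta_awareness by self_reflection, and redirect_breath jointly by
#' equanimity and breath_focus.
#'
#' @return Named list with one entry per state, each a list with `primary`
#'   and `secondary` character vectors of thoughtseed names.
#' @export
default_attractor_spec <- function() {
  list(
    breath_control = list(primary = "breath_focus", secondary = "equanimity"),
    mind_wandering = list(primary = c("pain_discomfort", "pending_tasks"),
                          secondary = character(0)),
    meta_awareness = list(primary = "self_reflection",
                          secondary = character(0)),
    redirect_breath = list(primary = c("equanimity", "breath_focus"),
                           secondary = character(0))
  )
}

validate_attractor_spec <- function(spec) {
  if (!is.list(spec) || !setequal(names(spec), meditation_states()))
    stop_vipassim("attractor spec must name every meditation state",
                  class = "vipassim_spec_error")
  for (s in names(spec)) {
    pri <- spec[[s]]$primary
    sec <- spec[[s]]$secondary %||% character(0)
    if (length(pri) < 1L)
      stop_vipassim("state '%s' needs at least one primary attractor", s,
                    class = "vipassim_spec_error")
    if (length(intersect(pri, sec)))
      stop_vipassim("state '%s' has overlapping primary/secondary sets", s,
                    class = "vipassim_spec_error")
    bad <- setdiff(c(pri, sec), thoughtseeds())
    if (length(bad))
      stop_vipassim("state '%s' names unknown thoughtseed(s): %s", s,
                    paste(bad, collapse = ", "),
                    class = "vipassim_spec_error")
  }
  invisible(spec)
}

#' Save or load a profile as YAML/JSON
#'
#' Round-trip serialization of an [make_profile()] bundle. The format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param profile An `expertise_profile`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `save_profile` returns `path` invisibly; `load_profile` returns a
#'   validated `expertise_profile` equal to the one saved.
#' @export
save_profile <- function(profile, path) {
  stopifnot(inherits(profile, "expertise_profile"))
  obj <- unclass(profile)
  obj$dwell_limits <- lapply(obj$dwell_limits, as.list)
  obj$transition_threshold <- as.list(obj$transition_threshold)
  obj$meta_coupling_beta <- as.list(obj$meta_coupling_beta)
  write_config_file(obj, path)
  invisible(path)
}

#' @rdname save_profile
#' @export
load_profile <- function(path) {
  obj <- read_config_file(path)
  lvl <- obj$level
  obj$level <- NULL
  obj$dwell_limits <- lapply(obj$dwell_limits, function(d) unlist(d))
  obj$transition_threshold <- unlist(obj$transition_threshold)
  obj$meta_coupling_beta <- unlist(obj$meta_coupling_beta)
  obj$responsiveness <- as.numeric(obj$responsiveness)
  obj$distraction_spike_range <- as.numeric(obj$distraction_spike_range)
  make_profile(lvl, overrides = obj)
}

write_config_file <- function(obj, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path, precision = 15)
  } else {
    stop_vipassim("unsupported config extension: '%s'", ext,
                  class = "vipassim_config_error")
  }
  invisible(path)
}

read_config_file <- function(path) {
  if (!file.exists(path))
    stop_vipassim("file not found: %s", path, class = "vipassim_config_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
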