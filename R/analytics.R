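#' Episode (dwell-time) statistics of a trace
#'
#' Partitions the state sequence into maximal constant-state runs and
#' summarizes their durations per state. The final, right-censored episode
#' counts as complete by default; `drop_censored = TRUE` excludes it.
#'
#' @param trace A trace data frame (see [train()], [run_simulation()]).
#' @param drop_censored Drop the trailing episode cut off by the end of the
#'   trace (default `FALSE`).
#' @return An `episode_stats`: list with `episodes` (data frame of state,
#'   start, duration), `per_state` (data frame of state, count, mean, sd,
#'   total), and `transition_kind_counts`.
#' @export
#' @examples
#' m <- train(make_profile("novice"), n_steps = 100, seed = 1)
#' episode_durations(m$trace)
episode_durations <- function(trace, drop_censored = FALSE) {
  if (is.null(trace) || nrow(trace) == 0)
    stop_vipassim("trace is empty", class = "vipassim_validation_error")
  r <- rle(trace$state)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  ep <- data.frame(state = r$values, start = starts, duration = r$lengths,
                   stringsAsFactors = FALSE)
  if (drop_censored && nrow(ep) > 1) ep <- ep[-nrow(ep), ]
  per_state <- do.call(rbind, lapply(meditation_states(), function(s) {
    d <- ep$duration[ep$state == s]
    data.frame(state = s, count = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) > 1) stats::sd(d) else NA_real_,
               total = sum(d), stringsAsFactors = FALSE)
  }))
  structure(
    list(episodes = ep, per_state = per_state,
         transition_kind_counts = table(factor(
           trace$transition_kind, levels = c("none", "natural", "forced")))),
    class = "episode_stats")
}

#' @export
print.episode_stats <- function(x, ...) {
  cat("<episode_stats>\n")
  print(x$per_state, row.names = FALSE)
  invisible(x)
}

#' State-conditioned activation summary
#'
#' Mean, min and max of each thoughtseed's activation over the timesteps
#' spent in one meditation state. A state never visited yields an empty
#' marker (`n = 0`, all statistics `NA`) rather than an error.
#'
#' @param trace A trace data frame.
#' @param state A meditation state name.
#' @return Data frame with one row per thoughtseed (columns thoughtseed,
#'   mean, min, max) plus attribute `n` (number of timesteps in the state).
#' @export
activation_summary <- function(trace, state) {
  stopifnot(state %in% meditation_states())
  A <- trace_activations(trace)[trace$state == state, , drop = FALSE]
  if (nrow(A) == 0) {
    out <- data.frame(thoughtseed = thoughtseeds(), mean = NA_real_,
                      min = NA_real_, max = NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      thoughtseed = thoughtseeds(),
      mean = colMeans(A), min = apply(A, 2, min), max = apply(A, 2, max),
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n") <- nrow(A)
  attr(out, "state") <- state
  out
}

#' Per-row total-variation distance between transition matrices
#'
#' `TV(row i) = 0.5 * sum_j |T_learned[i, j] - T_ref[i, j]|`, a number in
#' \[0, 1\] per state. Learned rows without any observed exits carry no
#' estimate and are returned as `NA`.
#'
#' @param learned A `transition_model` (see [train()]) or a 4x4
#'   row-stochastic matrix.
#' @param reference A `reference_transition_matrix` or a 4x4 matrix.
#' @return Named numeric vector of per-state total-variation distances.
#' @export
compare_transition_matrices <- function(learned, reference) {
  Tl <- if (inherits(learned, "transition_model")) learned$T else learned
  Tr <- if (inherits(reference, "reference_transition_matrix"))
    reference$matrix else reference
  stopifnot(all(dim(Tl) == c(4, 4)), all(dim(Tr) == c(4, 4)))
  tv <- vapply(meditation_states(), function(s) {
    if (any(is.na(Tl[s, ]))) return(NA_real_)
    0.5 * sum(abs(Tl[s, ] - Tr[s, ]))
  }, numeric(1))
  tv
}

mu_summary <- function(traces) {
  mu <- unlist(lapply(traces, function(tr) tr$mu))
  c(mean = mean(mu), min = min(mu), max = max(mu), sd = stats::sd(mu))
}

pooled_episode_mean <- function(traces, state, drop_censored = FALSE) {
  d <- unlist(lapply(traces, function(tr) {
    ep <- episode_durations(tr, drop_censored)$episodes
    ep$duration[ep$state == state]
  }))
  if (!length(d)) return(c(mean = NA_real_, count = 0))
  c(mean = mean(d), count = length(d))
}

level_summary <- function(traces, drop_censored = FALSE) {
  stats_by_state <- lapply(meditation_states(), function(s) {
    pe <- pooled_episode_mean(traces, s, drop_censored)
    act <- lapply(traces, activation_summary, state = s)
    ns <- vapply(act, function(a) attr(a, "n"), numeric(1))
    means <- vapply(seq_along(thoughtseeds()), function(i) {
      v <- vapply(act, function(a) a$mean[i], numeric(1))
      if (all(is.na(v))) NA_real_ else
        stats::weighted.mean(v, ns, na.rm = TRUE)
    }, numeric(1))
    list(state = s, episode_mean = unname(pe["mean"]),
         episode_count = unname(pe["count"]),
         activation_mean = stats::setNames(means, thoughtseeds()))
  })
  names(stats_by_state) <- meditation_states()
  list(n_traces = length(traces), by_state = stats_by_state,
       mu = mu_summary(traces))
}

#' Novice vs expert contrast report
#'
#' Aggregates ensembles of traces from the two expertise levels into a
#' deterministic report: pooled episode durations and counts per state,
#' state-conditioned activation means, meta-awareness summaries, and —
#' when learned models are supplied — the learned transition matrices and
#' their per-row total-variation divergence from the packaged empirical
#' reference.
#'
#' @param novice_traces,expert_traces Non-empty lists of trace data frames.
#' @param novice_model,expert_model Optional `learned_model` objects whose
#'   transition matrices are compared against the reference matrices.
#' @param drop_censored Passed to [episode_durations()].
#' @return A `contrast_report` list with elements `novice`, `expert` and
#'   `differences` (expert minus novice for headline quantities).
#' @export
contrast_report <- function(novice_traces, expert_traces,
                            novice_model = NULL, expert_model = NULL,
                            drop_censored = FALSE) {
  if (!length(novice_traces) || !length(expert_traces))
    stop_vipassim("each level needs at least one trace",
                  class = "vipassim_validation_error")
  nov <- level_summary(novice_traces, drop_censored)
  exp <- level_summary(expert_traces, drop_censored)
  if (!is.null(novice_model)) {
    nov$learned_T <- novice_model$transition_model$T
    nov$tv_vs_reference <- compare_transition_matrices(
      novice_model$transition_model, reference_transition_matrix("novice"))
  }
  if (!is.null(expert_model)) {
    exp$learned_T <- expert_model$transition_model$T
    exp$tv_vs_reference <- compare_transition_matrices(
      expert_model$transition_model, reference_transition_matrix("expert"))
  }
  diffs <- list(
    mu_mean = unname(exp$mu["mean"] - nov$mu["mean"]),
    mind_wandering_episode_mean =
      exp$by_state$mind_wandering$episode_mean -
      nov$by_state$mind_wandering$episode_mean,
    mind_wandering_episode_count =
      exp$by_state$mind_wandering$episode_count -
      nov$by_state$mind_wandering$episode_count,
    breath_focus_in_breath_control =
      unname(exp$by_state$breath_control$activation_mean["breath_focus"] -
             nov$by_state$breath_control$activation_mean["breath_focus"]))
  structure(list(novice = nov, expert = exp, differences = diffs),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("<contrast_report>\n")
  cat(sprintf("  traces: %d novice, %d expert\n",
              x$novice$n_traces, x$expert$n_traces))
  cat(sprintf("  mean meta-awareness : novice %.3f, expert %.3f\n",
              x$novice$mu["mean"], x$expert$mu["mean"]))
  cat(sprintf("  mind_wandering mean episode: novice %.1f, expert %.1f steps\n",
              x$novice$by_state$mind_wandering$episode_mean,
              x$expert$by_state$mind_wandering$episode_mean))
  cat(sprintf("  breath_focus in breath_control: novice %.3f, expert %.3f\n",
              x$novice$by_state$breath_control$activation_mean["breath_focus"],
              x$expert$by_state$breath_control$activation_mean["breath_focus"]))
  invisible(x)
}
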