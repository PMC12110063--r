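#' vipassim: agent-based simulation of attentional dynamics in meditation
#'
#' Five competing attentional agents ("thoughtseeds") generate four emergent
#' meditation states under winner-takes-all dominance, state-dependent
#' meta-awareness regulation and threshold/dwell-limited state transitions.
#' The package covers the full workflow: rule-based training ([train()]),
#' signed interaction-network extraction via lagged Granger causality
#' ([extract_network()]), simulation of the trained model ([run_simulation()]),
#' and trace analytics ([episode_durations()], [contrast_report()]).
#'
#' @keywords internal
"_PACKAGE"

#' Canonical thoughtseed names
#'
#' The five attentional agents, in canonical order. This order is the
#' tie-breaking order for winner-takes-all dominance and fixes the column
#' order of all weight and interaction matrices.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' thoughtseeds()
thoughtseeds <- function() {
  c("breath_focus", "equanimity", "pain_discomfort",
    "pending_tasks", "self_reflection")
}

#' Thoughtseed categories
#'
#' @return Named character vector mapping each thoughtseed to its category:
#'   focus, regulation, distraction or metacognition.
#' @export
thoughtseed_categories <- function() {
  c(breath_focus = "focus",
    equanimity = "regulation",
    pain_discomfort = "distraction",
    pending_tasks = "distraction",
    self_reflection = "metacognition")
}

#' The distraction thoughtseeds
#'
#' @return Character vector: the thoughtseeds in the distraction category.
#' @export
distraction_thoughtseeds <- function() {
  names(thoughtseed_categories())[thoughtseed_categories() == "distraction"]
}

#' Canonical meditation state names
#'
#' The four macroscopic attractor regimes, in canonical order. This order
#' fixes row/column order of all transition matrices and breaks ties when
#' several candidate states have equal attractor support.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' meditation_states()
meditation_states <- function() {
  c("breath_control", "mind_wandering", "meta_awareness", "redirect_breath")
}

## clip to the activation interval [lo, hi]
## (x first in pmax/pmin so names survive)
clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vipassim <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "vipassim_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
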