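run_config_fields <- function() {
  c("level", "n_steps", "seeds", "out_dir", "overrides", "noise_law",
    "drop_censored", "calibration_map", "max_lag")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file, rejects unknown keys, applies defaults and
#' validates the result. An empty file yields all defaults.
#'
#' Recognized keys: `level` (novice/expert, default novice), `n_steps`
#' (default 200), `seeds` (integer vector, default 1), `out_dir`
#' (default "."), `overrides` (profile field overrides, validated by
#' [make_profile()]), `noise_law` ("gaussian"/"uniform"), `drop_censored`
#' (logical), `calibration_map` ("linear"/"log10"), `max_lag` (default 5).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else read_config_file(path) %||% list()
  unknown <- setdiff(names(raw), run_config_fields())
  if (length(unknown))
    stop_vipassim("unknown config key(s): %s (valid: %s)",
                  paste(unknown, collapse = ", "),
                  paste(run_config_fields(), collapse = ", "),
                  class = "vipassim_config_error")
  cfg <- list(
    level = raw$level %||% "novice",
    n_steps = as.integer(raw$n_steps %||% 200L),
    seeds = as.integer(unlist(raw$seeds %||% 1L)),
    out_dir = raw$out_dir %||% ".",
    overrides = raw$overrides %||% list(),
    noise_law = raw$noise_law %||% "gaussian",
    drop_censored = isTRUE(raw$drop_censored),
    calibration_map = raw$calibration_map %||% "linear",
    max_lag = as.integer(raw$max_lag %||% 5L)
  )
  if (!cfg$level %in% c("novice", "expert"))
    stop_vipassim("invalid config field 'level': %s", cfg$level,
                  class = "vipassim_config_error")
  if (cfg$n_steps < 1)
    stop_vipassim("invalid config field 'n_steps': must be >= 1",
                  class = "vipassim_config_error")
  if (!cfg$calibration_map %in% c("linear", "log10"))
    stop_vipassim("invalid config field 'calibration_map'",
                  class = "vipassim_config_error")
  if (!cfg$noise_law %in% c("gaussian", "uniform"))
    stop_vipassim("invalid config field 'noise_law'",
                  class = "vipassim_config_error")
  if (cfg$max_lag < 1)
    stop_vipassim("invalid config field 'max_lag': must be >= 1",
                  class = "vipassim_config_error")
  ## profile overrides are validated by the profile constructor
  cfg$overrides$noise_law <- cfg$overrides$noise_law %||% cfg$noise_law
  invisible(make_profile(cfg$level, cfg$overrides))
  structure(cfg, class = "run_config")
}

config_profile <- function(cfg) make_profile(cfg$level, cfg$overrides)

#' Derive a per-stage child seed from a run seed
#'
#' One global seed is expanded into deterministic per-stage seeds (stages:
#' train = 1, network = 2, simulate = 3, report = 4) via a fixed
#' Lehmer-style mix modulo 2^31 - 1, so each pipeline stage is individually
#' reproducible from the run seed alone.
#'
#' @param seed Integer run seed.
#' @param stage Stage name or integer offset.
#' @return Integer child seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, stage) {
  stages <- c(train = 1, network = 2, simulate = 3, report = 4)
  off <- if (is.character(stage)) {
    if (!stage %in% names(stages))
      stop_vipassim("unknown stage '%s'", stage,
                    class = "vipassim_config_error")
    stages[[stage]]
  } else as.numeric(stage)
  m <- 2147483647
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + off * 7919) %% m
  as.integer(max(1, x))
}

## FNV-1a hash of a config, for embedding in output artifacts so a run can
## be matched to the exact configuration that produced it.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

trace_columns <- function() {
  c("t", "state", "dominant", "mu", paste0("alpha_", thoughtseeds()),
    "transition_kind")
}

#' Write / read a trace as CSV
#'
#' Fixed column order: t, state, dominant, mu, the five `alpha_<thoughtseed>`
#' columns, transition_kind. Trace attributes (level, seed) travel in a
#' sidecar of the run's `run_info.json`, not in the CSV.
#'
#' @param trace A trace data frame.
#' @param path Output CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   trace data frame.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)[, trace_columns()]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trace_columns(), names(df))
  if (length(missing))
    stop_vipassim("trace file lacks column(s): %s",
                  paste(missing, collapse = ", "),
                  class = "vipassim_validation_error")
  class(df) <- c("meditation_trace", "data.frame")
  df
}

write_transition_matrix_json <- function(model, path, meta = list()) {
  tm <- model$transition_model
  obj <- c(list(states = meditation_states(),
                matrix = unname(unclass(tm$T)),
                counts = unname(unclass(tm$counts)),
                n_natural = tm$n_natural, n_forced = tm$n_forced), meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

write_weights_json <- function(model, path, meta = list()) {
  W <- unclass(model$weight_matrix)
  obj <- c(list(states = rownames(W), thoughtseeds = colnames(W),
                weights = unname(W),
                omega_base = attr(model$weight_matrix, "omega_base")), meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an interaction network as JSON (node/edge list) and adjacency CSV
#'
#' @param network An `interaction_matrix`.
#' @param json_path,csv_path Output paths (`NULL` to skip one of them).
#' @param meta Extra top-level JSON fields (e.g. seed, config hash).
#' @return Invisibly, the JSON path.
#' @export
write_network <- function(network, json_path, csv_path = NULL, meta = list()) {
  W <- network$weights
  edges <- list()
  for (src in rownames(W)) for (tgt in colnames(W)) {
    if (W[src, tgt] != 0) {
      p <- network$granger[[paste0(src, "->", tgt)]]$p_value %||% NA
      edges[[length(edges) + 1L]] <-
        list(source = src, target = tgt, weight = W[src, tgt], p_value = p)
    }
  }
  obj <- c(list(nodes = thoughtseeds(), edges = edges), meta)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(W), csv_path, row.names = TRUE)
  invisible(json_path)
}
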