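#' Pairwise lagged Granger-causality test
#'
#' Tests whether the past of `x` improves prediction of `y` beyond `y`'s own
#' past. Two least-squares autoregressions are fitted over the same
#' `length(y) - max_lag` usable observations: a restricted model of y on its
#' own `max_lag` lags, and an unrestricted model adding `max_lag` lags of x.
#' The Granger statistic is the relative residual-sum-of-squares reduction
#' `G = (RSS_restricted - RSS_unrestricted) / RSS_unrestricted`, and the
#' p-value comes from the likelihood-ratio statistic
#' `n_eff * log(RSS_restricted / RSS_unrestricted)` referred to a
#' chi-squared distribution with `max_lag` degrees of freedom. The sign of
#' the influence is the sign of the summed cross-lag coefficients of the
#' unrestricted model.
#'
#' @param x,y Equal-length numeric series; `length > 3 * max_lag` required.
#' @param max_lag Maximum lag L in timesteps (default 5).
#' @param source,target Optional thoughtseed labels carried into the result.
#' @return A `granger_result`: list with `source`, `target`, `G` (>= 0),
#'   `p_value`, `sign` (+1/-1), `coef_sum`, `max_lag`, `n_eff`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(300)
#' y <- c(0, 0.9 * x[-300]) + rnorm(300, sd = 0.1)
#' granger_pair(x, y)$p_value  # far below 0.05
granger_pair <- function(x, y, max_lag = 5, source = "x", target = "y") {
  if (length(x) != length(y))
    stop_vipassim("series must have equal length",
                  class = "vipassim_validation_error")
  n <- length(y)
  if (n <= 3 * max_lag)
    stop_vipassim("series too short: need length > 3 * max_lag = %d",
                  3 * max_lag, class = "vipassim_validation_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_vipassim("series must be finite", class = "vipassim_validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_vipassim("degenerate series: zero variance",
                  class = "vipassim_degenerate_error")

  lagmat <- function(v) {
    sapply(seq_len(max_lag), function(l) v[(max_lag - l + 1):(n - l)])
  }
  yy <- y[(max_lag + 1):n]
  Yl <- lagmat(y)
  Xl <- lagmat(x)
  n_eff <- length(yy)

  fit_r <- stats::lm.fit(cbind(1, Yl), yy)
  fit_u <- stats::lm.fit(cbind(1, Yl, Xl), yy)
  rss_r <- sum(fit_r$residuals^2)
  rss_u <- sum(fit_u$residuals^2)
  if (rss_u < 1e-12 || rss_r < 1e-12)
    stop_vipassim("degenerate series: zero-variance residuals",
                  class = "vipassim_degenerate_error")

  G <- max(0, (rss_r - rss_u) / rss_u)
  stat <- n_eff * log(rss_r / rss_u)
  p <- stats::pchisq(stat, df = max_lag, lower.tail = FALSE)
  coef_sum <- sum(fit_u$coefficients[(max_lag + 2):(2 * max_lag + 1)],
                  na.rm = TRUE)
  structure(
    list(source = source, target = target, G = G, p_value = p,
         sign = if (coef_sum >= 0) 1 else -1, coef_sum = coef_sum,
         max_lag = max_lag, n_eff = n_eff),
    class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result> %s -> %s: G = %.4f, p = %.3g (L = %d)\n",
              x$source, x$target, x$G, x$p_value, x$max_lag))
  invisible(x)
}

#' Calibrate Granger results into signed causal weights
#'
#' Maps each pairwise test into a causal weight: zero when p >= 0.05;
#' otherwise magnitude `(1 - p / 0.05) * 0.7` (the default `"linear"` map,
#' monotone decreasing in p and bounded by 0.7), signed by the summed
#' cross-lag coefficients. Weak connections with magnitude below 0.1 are
#' filtered to zero. An alternative `"log10"` map,
#' `0.7 * min(1, log10(0.05 / p) / 3)`, is provided for sensitivity checks.
#'
#' @param results List of `granger_result` objects covering all 20 ordered
#'   thoughtseed pairs.
#' @param map `"linear"` (default) or `"log10"`.
#' @return 5x5 signed causal weight matrix (rows = source, cols = target),
#'   zero diagonal, entries in \[-0.7, 0.7\].
#' @export
calibrate_strengths <- function(results, map = c("linear", "log10")) {
  map <- match.arg(map)
  ts <- thoughtseeds()
  M <- matrix(0, 5, 5, dimnames = list(ts, ts))
  seen <- character(0)
  for (r in results) {
    stopifnot(inherits(r, "granger_result"))
    seen <- c(seen, paste0(r$source, "->", r$target))
    if (r$p_value >= 0.05) next
    mag <- switch(map,
      linear = (1 - r$p_value / 0.05) * 0.7,
      log10 = 0.7 * min(1, log10(0.05 / r$p_value) / 3))
    if (mag < 0.1) mag <- 0
    M[r$source, r$target] <- r$sign * mag
  }
  pairs <- outer(ts, ts, function(a, b) paste0(a, "->", b))
  required <- pairs[row(pairs) != col(pairs)]
  missing <- setdiff(required, seen)
  if (length(missing))
    stop_vipassim("results must cover all ordered pairs; missing: %s",
                  paste(utils::head(missing, 3), collapse = ", "),
                  class = "vipassim_validation_error")
  M
}

#' Zero-lag baseline correlations between thoughtseed activations
#'
#' Pearson correlation of each ordered pair of activation series, with the
#' diagonal zeroed. A zero-variance series cannot carry correlation
#' structure; its row and column are set to 0 with a warning.
#'
#' @param trace A trace data frame (see [train()]), or a numeric matrix of
#'   activations with thoughtseed columns; at least 10 timesteps.
#' @return 5x5 correlation matrix with zero diagonal.
#' @export
baseline_correlations <- function(trace) {
  A <- if (is.matrix(trace)) trace else trace_activations(trace)
  if (nrow(A) < 10)
    stop_vipassim("trace must have at least 10 timesteps",
                  class = "vipassim_validation_error")
  sds <- apply(A, 2, stats::sd)
  C <- matrix(0, ncol(A), ncol(A), dimnames = list(colnames(A), colnames(A)))
  ok <- sds > 0
  if (any(!ok))
    warning(sprintf("zero-variance series zeroed in baseline correlations: %s",
                    paste(colnames(A)[!ok], collapse = ", ")))
  if (sum(ok) >= 2) C[ok, ok] <- stats::cor(A[, ok, drop = FALSE])
  diag(C) <- 0
  C
}

#' Combine causal weights with baseline correlations
#'
#' Blends the calibrated causal weights (70%) with the zero-lag baseline
#' correlations (30%), zeroes entries whose combined magnitude does not
#' exceed 0.15, and rescales the surviving entries by
#' `min(1, 0.6 / max |combined|)` so the final network lies in
#' \[-0.6, 0.6\] while preserving the ratios between edges. The causal,
#' baseline and pre-threshold combined matrices are retained for audit.
#'
#' @param causal 5x5 causal weight matrix (see [calibrate_strengths()]).
#' @param baseline 5x5 baseline correlation matrix
#'   (see [baseline_correlations()]).
#' @return An `interaction_matrix`: list with `weights` (final 5x5 signed
#'   network, zero diagonal, max magnitude <= 0.6) and `provenance`
#'   (list of `causal`, `baseline`, `combined`).
#' @export
combine_and_scale <- function(causal, baseline) {
  stopifnot(is.matrix(causal), is.matrix(baseline),
            all(dim(causal) == dim(baseline)),
            all(abs(diag(causal)) < 1e-12), all(abs(diag(baseline)) < 1e-12))
  combined <- 0.7 * causal + 0.3 * baseline
  W <- combined
  W[abs(W) <= 0.15] <- 0
  if (any(W != 0)) {
    s <- min(1, 0.6 / max(abs(W)))
    W <- W * s
  }
  structure(
    list(weights = W,
         provenance = list(causal = causal, baseline = baseline,
                           combined = combined)),
    class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf("<interaction_matrix> %d directed edges (max |w| = %.3f)\n",
              nz, if (nz) max(abs(x$weights)) else 0))
  print(round(x$weights, 3))
  invisible(x)
}

#' Extract the signed thoughtseed interaction network from a trace
#'
#' Full pipeline: pairwise lagged Granger tests over all 20 ordered
#' thoughtseed pairs ([granger_pair()]), calibration of significant tests
#' into signed causal weights ([calibrate_strengths()]), zero-lag baseline
#' correlations ([baseline_correlations()]), and weighted combination with
#' thresholding and scaling ([combine_and_scale()]). Pairs whose regressions
#' are degenerate (a clipped, near-constant activation series) carry no
#' causal evidence and enter the calibration with p = 1.
#'
#' @param trace A trace data frame or activation matrix.
#' @param max_lag Maximum lag L (default 5).
#' @param map Calibration map, see [calibrate_strengths()].
#' @return An `interaction_matrix` whose `granger` field holds the 20
#'   pairwise test results.
#' @export
extract_network <- function(trace, max_lag = 5, map = "linear") {
  A <- if (is.matrix(trace)) trace else trace_activations(trace)
  ts <- colnames(A)
  results <- list()
  for (src in ts) for (tgt in ts) {
    if (src == tgt) next
    r <- tryCatch(
      granger_pair(A[, src], A[, tgt], max_lag = max_lag,
                   source = src, target = tgt),
      vipassim_degenerate_error = function(e) {
        structure(list(source = src, target = tgt, G = 0, p_value = 1,
                       sign = 1, coef_sum = 0, max_lag = max_lag,
                       n_eff = nrow(A) - max_lag),
                  class = "granger_result")
      })
    results[[paste0(src, "->", tgt)]] <- r
  }
  causal <- calibrate_strengths(results, map = map)
  base <- baseline_correlations(A)
  net <- combine_and_scale(causal, base)
  net$granger <- results
  net
}
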