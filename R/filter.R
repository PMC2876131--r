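# High-level wrapper: replicate correlations -> mixture fit -> selection,
# the full probe-filtering procedure in one call.

#' Filter non-variable probes from a replicated beta matrix
#'
#' Runs the complete selection procedure: per-probe replicate correlations,
#' a K-component Gaussian mixture fitted to the defined correlations, probe
#' posteriors, and selection of the variable-class probes at the posterior
#' threshold.
#'
#' @inheritParams probe_correlations
#' @inheritParams fit_mixture
#' @param threshold Posterior cutoff for selection (default 0.5).
#' @param ... Further arguments passed to [fit_mixture()].
#' @return An object of class `mvp_filter` with elements
#'   `probe_correlations`, `sample_correlations`, `diagnostics`, `model`,
#'   `posteriors`, `selection`.
#' @examples
#' sim <- generate_dataset(simulation_config(n_probes = 200, n_samples = 60,
#'                                           n_replicate_pairs = 30, seed = 7))
#' fit <- mvp_filter(sim$betas, sim$design, seed = 7)
#' fit
#' @export
mvp_filter <- function(betas, design, K = 2L, threshold = 0.5,
                       min_pairs = 10L, seed = 1L, ...) {
  pct <- probe_correlations(betas, design, min_pairs = min_pairs)
  sct <- sample_correlations(betas, design)
  model <- fit_mixture(pct$r[pct$defined], K = K, seed = seed, ...)
  post <- posteriors(model, pct)
  sel <- select_probes(post, threshold = threshold)
  out <- list(
    probe_correlations = pct,
    sample_correlations = sct,
    diagnostics = diagnostics(pct, sct),
    model = model,
    posteriors = post,
    selection = sel
  )
  class(out) <- "mvp_filter"
  out
}

#' @export
print.mvp_filter <- function(x, ...) {
  print(x$diagnostics)
  print(x$model)
  print(x$selection)
  invisible(x)
}

#' @export
summary.mvp_filter <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.mvp_filter <- function(x, ...) {
  plot(x$model, ...)
  graphics::abline(v = x$model$means, lty = 3)
  invisible(x)
}
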