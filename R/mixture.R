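# Univariate Gaussian mixture fitted by Expectation-Maximization, the
# classifier at the heart of the probe filter. The probe-correlation
# distribution is modelled as K normal components; the lowest-mean
# component collects the non-variable probes (replicate correlation near
# zero) and probes are excluded or retained by posterior probability.

# One EM run from an explicit initialization. Returns parameters, the full
# log-likelihood trace (monotone up to floating point), and convergence
# status. Responsibilities are computed in log space for stability.
em_run <- function(x, weights, means, variances, tol, max_iter,
                   variance_floor) {
  n <- length(x)
  K <- length(means)
  ll_trace <- numeric(0L)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    logdens <- vapply(seq_len(K), function(k) {
      log(weights[k]) + stats::dnorm(x, means[k], sqrt(variances[k]),
                                     log = TRUE)
    }, numeric(n))
    mx <- apply(logdens, 1L, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    gamma <- exp(logdens - lse)
    nk <- colSums(gamma)
    weights <- nk / n
    means <- colSums(gamma * x) / nk
    variances <- pmax(
      colSums(gamma * (outer(x, means, "-")^2)) / nk,
      variance_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = weights, means = means, variances = variances,
       log_likelihood = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       n_iterations = iter, converged = converged)
}

# Quantile-spread initialization with seeded jitter; restart r = 0 is the
# unjittered quantile placement.
em_init <- function(x, K, restart) {
  mu <- stats::quantile(x, probs = seq_len(K) / (K + 1), names = FALSE,
                        type = 7)
  if (restart > 0L) {
    mu <- mu + stats::rnorm(K, sd = max(stats::sd(x), 1e-3) * 0.25)
  }
  list(weights = rep(1 / K, K), means = sort(mu),
       variances = rep(max(stats::var(x) * (length(x) - 1) / length(x),
                           1e-6), K))
}

#' Fit a univariate Gaussian mixture by Expectation-Maximization
#'
#' Models a vector of probe correlations as a K-component normal mixture.
#' The E-step computes each value's posterior responsibility under the
#' current parameters; the M-step re-estimates mixing proportions, means and
#' variances from the responsibilities; the cycle repeats until the relative
#' log-likelihood change falls below `tol`. Multiple seeded restarts
#' (quantile-placed means with jitter, equal weights, pooled variance) guard
#' against local optima; the best log-likelihood wins. Components are stored
#' sorted by ascending mean, so component 1 is always the candidate
#' non-variable class.
#'
#' @param values Numeric vector (correlations); `NA`s are dropped.
#' @param K Number of components (>= 1).
#' @param seed Integer seed controlling restart jitter.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of random restarts.
#' @param variance_floor Lower bound on component variances.
#' @param extra_inits Optional list of additional initializations (each a
#'   list with `weights`, `means`, `variances`); used internally for warm
#'   starts.
#' @return An object of class `mvp_mixture` with elements `K`, `weights`,
#'   `means`, `variances`, `log_likelihood`, `ll_trace`, `aic`, `bic`,
#'   `n_iterations`, `converged`, `n_restarts_used`, `seed`, `n`, `data`.
#' @export
fit_mixture <- function(values, K = 2L, seed = 1L, tol = 1e-8,
                        max_iter = 1000L, n_restarts = 10L,
                        variance_floor = 1e-6, extra_inits = NULL) {
  K <- stopifnot_scalar_count(K, "K")
  n_restarts <- stopifnot_scalar_count(n_restarts, "n_restarts")
  max_iter <- stopifnot_scalar_count(max_iter, "max_iter")
  x <- as.numeric(values[!is.na(values)])
  n <- length(x)
  if (n < 2L * K) {
    mvp_stop(sprintf("need at least %d defined values to fit K = %d", 2L * K, K))
  }
  if (K > 1L && stats::sd(x) == 0) {
    mvp_stop("all values identical: cannot fit more than one component",
             class = "mvp_numeric_error")
  }

  best <- NULL
  with_seed(seed, {
    inits <- c(lapply(seq_len(n_restarts) - 1L, function(r) em_init(x, K, r)),
               extra_inits)
    for (init in inits) {
      fit <- em_run(x, init$weights, init$means, init$variances,
                    tol = tol, max_iter = max_iter,
                    variance_floor = variance_floor)
      if (is.null(best) || fit$log_likelihood > best$log_likelihood) {
        best <- fit
      }
    }
  })

  ord <- order(best$means)
  n_par <- 3L * K - 1L
  out <- list(
    K = K,
    weights = best$weights[ord],
    means = best$means[ord],
    variances = best$variances[ord],
    log_likelihood = best$log_likelihood,
    ll_trace = best$ll_trace,
    aic = 2 * n_par - 2 * best$log_likelihood,
    bic = n_par * log(n) - 2 * best$log_likelihood,
    n_iterations = best$n_iterations,
    converged = best$converged,
    n_restarts_used = as.integer(n_restarts),
    seed = seed,
    n = n,
    data = x
  )
  class(out) <- "mvp_mixture"
  out
}

#' @export
print.mvp_mixture <- function(x, ...) {
  cat(sprintf("%d-component Gaussian mixture (n = %d, logLik = %.3f)\n",
              x$K, x$n, x$log_likelihood))
  print(round(coef(x), 4))
  if (!x$converged) cat("  warning: EM did not converge\n")
  invisible(x)
}

#' @export
coef.mvp_mixture <- function(object, ...) {
  m <- cbind(weight = object$weights, mean = object$means,
             sd = sqrt(object$variances))
  rownames(m) <- paste0("class", seq_len(object$K))
  m
}

#' @export
logLik.mvp_mixture <- function(object, ...) {
  structure(object$log_likelihood, df = 3L * object$K - 1L,
            nobs = object$n, class = "logLik")
}

#' @export
summary.mvp_mixture <- function(object, ...) {
  structure(list(model = object, coef = coef(object)),
            class = "summary.mvp_mixture")
}

#' @export
print.summary.mvp_mixture <- function(x, ...) {
  print(x$model)
  cat(sprintf("AIC %.2f  BIC %.2f  iterations %d  restarts %d\n",
              x$model$aic, x$model$bic, x$model$n_iterations,
              x$model$n_restarts_used))
  invisible(x)
}

#' Posterior class probabilities for new values
#'
#' @param object A fitted `mvp_mixture`.
#' @param newdata Numeric vector of values; defaults to the training data.
#' @param ... Unused.
#' @return Matrix (length(newdata) x K) of posterior probabilities, columns
#'   in ascending-mean component order.
#' @export
predict.mvp_mixture <- function(object, newdata = object$data, ...) {
  x <- as.numeric(newdata)
  K <- object$K
  logdens <- vapply(seq_len(K), function(k) {
    log(object$weights[k]) +
      stats::dnorm(x, object$means[k], sqrt(object$variances[k]), log = TRUE)
  }, numeric(length(x)))
  logdens <- matrix(logdens, ncol = K)
  mx <- apply(logdens, 1L, max)
  post <- exp(logdens - (mx + log(rowSums(exp(logdens - mx)))))
  post[is.na(x), ] <- NA_real_
  colnames(post) <- paste0("class", seq_len(K))
  post
}

#' @export
plot.mvp_mixture <- function(x, breaks = 40, main = "Mixture fit", ...) {
  h <- graphics::hist(x$data, breaks = breaks, freq = FALSE, main = main,
                      xlab = "probe correlation", ...)
  grid <- seq(min(h$breaks), max(h$breaks), length.out = 400)
  total <- rep(0, length(grid))
  for (k in seq_len(x$K)) {
    dk <- x$weights[k] * stats::dnorm(grid, x$means[k], sqrt(x$variances[k]))
    graphics::lines(grid, dk, lty = 2)
    total <- total + dk
  }
  graphics::lines(grid, total, lwd = 2)
  invisible(x)
}

#' @export
simulate.mvp_mixture <- function(object, nsim = object$n, seed = NULL, ...) {
  draw <- function() {
    k <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
    stats::rnorm(nsim, object$means[k], sqrt(object$variances[k]))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Fit mixtures across a range of component counts
#'
#' Fits one mixture per K under a shared seed policy and reports
#' log-likelihood, AIC and BIC, the fit indices used to judge how many
#' classes the correlation distribution supports. Each K > min re-uses the
#' previous solution (best component split in two) as an extra warm start,
#' so the best-of-restarts log-likelihood is non-decreasing in K.
#'
#' @inheritParams fit_mixture
#' @param K_range Integer vector of component counts (default `1:6`).
#' @return Data frame with columns `K`, `log_likelihood`, `aic`, `bic`,
#'   `converged`, sorted by `K`; fitted models in attribute `models`.
#' @export
scan_class_counts <- function(values, K_range = 1:6, seed = 1L, tol = 1e-8,
                              max_iter = 1000L, n_restarts = 10L,
                              variance_floor = 1e-6) {
  K_range <- sort(unique(as.integer(K_range)))
  models <- vector("list", length(K_range))
  prev <- NULL
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    warm <- NULL
    if (!is.null(prev) && prev$K == K - 1L) {
      split_k <- which.max(prev$weights)
      eps <- sqrt(prev$variances[split_k]) / 2
      warm <- list(list(
        weights = c(prev$weights[-split_k], rep(prev$weights[split_k] / 2, 2)),
        means = c(prev$means[-split_k], prev$means[split_k] - eps,
                  prev$means[split_k] + eps),
        variances = c(prev$variances[-split_k],
                      rep(prev$variances[split_k], 2))
      ))
    }
    models[[i]] <- fit_mixture(values, K = K, seed = seed, tol = tol,
                               max_iter = max_iter, n_restarts = n_restarts,
                               variance_floor = variance_floor,
                               extra_inits = warm)
    prev <- models[[i]]
  }
  out <- data.frame(
    K = K_range,
    log_likelihood = vapply(models, `[[`, numeric(1L), "log_likelihood"),
    aic = vapply(models, `[[`, numeric(1L), "aic"),
    bic = vapply(models, `[[`, numeric(1L), "bic"),
    converged = vapply(models, `[[`, logical(1L), "converged")
  )
  attr(out, "models") <- models
  out
}

#' Posterior class membership for probes
#'
#' Applies a fitted mixture to a probe-correlation table. Probes with an
#' undefined correlation (too few pairs or zero variance) are deterministic
#' members of the lowest-mean (non-variable) class: a probe without variance
#' across samples is non-variable by definition and never enters the
#' likelihood.
#'
#' @param model A fitted `mvp_mixture`.
#' @param pct A [probe_correlations()] table, or a numeric vector of
#'   correlations (NA = undefined).
#' @return A data frame of class `posterior_table`: `probe_id`, one
#'   `classk` posterior column per component, `assigned` (argmax class) and
#'   `defined`.
#' @export
posteriors <- function(model, pct) {
  stopifnot(inherits(model, "mvp_mixture"))
  if (is.numeric(pct)) {
    pct <- data.frame(probe_id = if (is.null(names(pct)))
      paste0("probe", seq_along(pct)) else names(pct),
      r = as.numeric(pct), defined = !is.na(pct),
      stringsAsFactors = FALSE)
  }
  post <- predict(model, pct$r)
  undef <- !pct$defined | is.na(pct$r)
  post[undef, ] <- 0
  post[undef, 1L] <- 1
  out <- data.frame(probe_id = pct$probe_id, post,
                    assigned = max.col(post, ties.method = "first"),
                    defined = !undef, stringsAsFactors = FALSE)
  class(out) <- c("posterior_table", "data.frame")
  out
}

#' Select variable probes by posterior probability
#'
#' A probe is selected when its posterior probability of belonging to the
#' variable side of the mixture — every component except the lowest-mean
#' one — is at least `threshold`. Ties at exactly the threshold are
#' selected. With K = 2 this is the posterior for the high-mean class.
#'
#' @param post A [posteriors()] table.
#' @param threshold Posterior cutoff in (0, 1], default 0.5.
#' @return An object of class `mvp_selection`: `threshold`, `selected`
#'   (probe ids), `n_selected`, `n_excluded`, `mask` (named logical).
#' @export
select_probes <- function(post, threshold = 0.5) {
  stopifnot(inherits(post, "posterior_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    mvp_stop("'threshold' must be in (0, 1]")
  }
  classes <- grep("^class[0-9]+$", names(post), value = TRUE)
  p_var <- if (length(classes) == 1L) {
    rep(0, nrow(post))  # K = 1: no variable side exists
  } else {
    rowSums(post[, classes[-1L], drop = FALSE])
  }
  mask <- post$defined & p_var >= threshold
  names(mask) <- post$probe_id
  out <- list(threshold = threshold,
              selected = post$probe_id[mask],
              n_selected = sum(mask),
              n_excluded = sum(!mask),
              mask = mask)
  class(out) <- "mvp_selection"
  out
}

#' @export
print.mvp_selection <- function(x, ...) {
  cat(sprintf(
    "Probe selection at posterior >= %.3g: %d selected, %d excluded\n",
    x$threshold, x$n_selected, x$n_excluded))
  invisible(x)
}

#' Serialize a fitted mixture to JSON
#'
#' Fields: `k`, `weights`, `means`, `variances`, `log_likelihood`, `aic`,
#' `bic`, `converged`, `seed`.
#'
#' @param model A fitted `mvp_mixture`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mixture_json <- function(model, path) {
  stopifnot(inherits(model, "mvp_mixture"))
  obj <- list(k = model$K, weights = model$weights, means = model$means,
              variances = model$variances,
              log_likelihood = model$log_likelihood, aic = model$aic,
              bic = model$bic, converged = model$converged,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted mixture from JSON
#'
#' @param path Path written by [write_mixture_json()].
#' @return An `mvp_mixture` (without training data or trace).
#' @export
read_mixture_json <- function(path) {
  if (!file.exists(path)) mvp_missing_input(path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(K = as.integer(obj$k), weights = obj$weights,
              means = obj$means, variances = obj$variances,
              log_likelihood = obj$log_likelihood, ll_trace = NULL,
              aic = obj$aic, bic = obj$bic, n_iterations = NA_integer_,
              converged = isTRUE(obj$converged),
              n_restarts_used = NA_integer_, seed = obj$seed,
              n = NA_integer_, data = NULL)
  class(out) <- "mvp_mixture"
  out
}
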