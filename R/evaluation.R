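# Downstream evaluation: per-probe regression F-tests against a continuous
# outcome, estimation of the proportion of null probes p0, positive false
# discovery rate q-values, and the Bonferroni threshold utility. Together
# these quantify the power gained by excluding non-variable probes.

#' Per-probe association scan against a continuous outcome
#'
#' Simple linear regression of the outcome on each probe's beta values over
#' complete cases, summarized by the F statistic
#' `F = (n - 2) R^2 / (1 - R^2)` on (1, n - 2) degrees of freedom and its
#' upper-tail p-value. Probes with zero variance among complete cases (or
#' fewer than 4 complete cases) get `F = 0`, `p = 1` and are flagged;
#' perfect fits are capped at the largest representable F and smallest
#' representable p and flagged.
#'
#' @param betas A [beta_matrix()].
#' @param outcomes An [outcome_table()], or a named numeric vector keyed by
#'   sample id.
#' @param outcome Outcome column name when `outcomes` is a table.
#' @param selection Optional [select_probes()] result restricting the scan
#'   to the selected probes.
#' @return A data frame of class `association_table` with columns
#'   `probe_id`, `F`, `p`, `n_used`, `flag`; attributes `outcome` and `m`
#'   (number of tests).
#' @export
association_scan <- function(betas, outcomes, outcome = NULL,
                             selection = NULL) {
  stopifnot(inherits(betas, "beta_matrix"))
  if (inherits(outcomes, "outcome_table") || is.data.frame(outcomes)) {
    if (is.null(outcome)) {
      cols <- setdiff(names(outcomes), "sample_id")
      if (length(cols) != 1L) mvp_stop("specify 'outcome' column name")
      outcome <- cols
    }
    y <- outcomes[[outcome]]
    names(y) <- outcomes$sample_id
  } else {
    y <- outcomes
    if (is.null(names(y))) mvp_stop("outcome vector must be named by sample id")
    if (is.null(outcome)) outcome <- "outcome"
  }
  common <- intersect(colnames(betas), names(y)[!is.na(y)])
  if (length(common) < 4L) {
    mvp_stop("need at least 4 samples with both probe values and outcome")
  }
  mat <- unclass(betas)[, common, drop = FALSE]
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "mvp_selection"))
    keep <- intersect(rownames(mat), selection$selected)
    mat <- mat[keep, , drop = FALSE]
  }
  yy <- y[common]

  obs <- !is.na(mat)
  n <- rowSums(obs)
  ymat <- matrix(yy, nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE)
  ymat[!obs] <- 0
  xm <- ifelse(obs, mat, 0)
  sx <- rowSums(xm); sy <- rowSums(ymat)
  sxx <- rowSums(xm^2); syy <- rowSums(ymat^2); sxy <- rowSums(xm * ymat)
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cv <- sxy - sx * sy / n
  scale <- pmax(sxx, 1e-300)
  zero_var <- (vx <= 1e-12 * scale) | (vy <= 0) | (n < 4L)
  r2 <- ifelse(zero_var, 0, cv^2 / (vx * vy))
  r2 <- pmin(r2, 1)
  perfect <- !zero_var & (1 - r2 < 1e-12)
  Fstat <- ifelse(zero_var, 0,
                  ifelse(perfect, .Machine$double.xmax,
                         (n - 2) * r2 / (1 - r2)))
  p <- ifelse(zero_var, 1,
              ifelse(perfect, .Machine$double.xmin,
                     stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)))
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(
    probe_id = rownames(mat),
    F = Fstat,
    p = p,
    n_used = as.integer(n),
    flag = ifelse(zero_var, "zero_variance", ifelse(perfect, "perfect_fit", "")),
    stringsAsFactors = FALSE
  )
  attr(out, "outcome") <- outcome
  attr(out, "m") <- nrow(out)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Critical value for the Meinshausen-Rice bounding function
#'
#' Monte-Carlo calibration of the constant `c(alpha, m)` so that, under m
#' independent uniform p-values, the supremum over the observed p-values of
#' `(Fhat(t) - t) / sqrt(t (1 - t))` exceeds `c` with probability `alpha`.
#'
#' @param alpha Exceedance level (default 0.05).
#' @param m Number of tests.
#' @param n_sim Monte-Carlo replicates (default 500).
#' @param seed Seed for the calibration draws.
#' @return A single non-negative constant.
#' @export
mr_critical_value <- function(alpha = 0.05, m, n_sim = 500L, seed = 1L) {
  m <- stopifnot_scalar_count(m, "m")
  n_sim <- stopifnot_scalar_count(n_sim, "n_sim")
  sup <- with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      p <- sort(stats::runif(m))
      max((seq_len(m) / m - p) / sqrt(p * (1 - p)))
    }, numeric(1L))
  })
  stats::quantile(sup, probs = 1 - alpha, names = FALSE, type = 7)
}

#' Estimate the proportion of true null hypotheses
#'
#' `method = "meinshausen-rice"` uses the bounding-function estimator
#' `p0 = 1 - sup_t (Fhat(t) - t - beta_m(t)) / (1 - t)` with
#' `beta_m(t) = c(alpha, m) sqrt(t (1 - t))`, the constant calibrated by
#' seeded Monte-Carlo simulation of the uniform empirical process
#' ([mr_critical_value()]) and the supremum taken over the observed
#' p-values. The estimate may exceed 1 and is not clipped unless
#' `clip = TRUE`. `method = "storey"` is the cross-check
#' `p0 = #\{p > lambda\} / (m (1 - lambda))`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param method `"meinshausen-rice"` (default) or `"storey"`.
#' @param alpha Calibration level for the bounding function.
#' @param lambda Storey tuning parameter (default 0.5).
#' @param n_sim,seed Monte-Carlo settings for the calibration.
#' @param c_alpha Optional precomputed critical value (skips calibration).
#' @param clip If `TRUE`, cap the estimate at 1.
#' @return A list of class `p0_estimate` with `p0`, `method`, `settings`.
#' @export
estimate_p0 <- function(p_values, method = c("meinshausen-rice", "storey"),
                        alpha = 0.05, lambda = 0.5, n_sim = 500L, seed = 1L,
                        c_alpha = NULL, clip = FALSE) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    mvp_stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  if (m < 10L) mvp_stop("need at least 10 p-values")
  if (method == "storey") {
    p0 <- sum(p > lambda) / (m * (1 - lambda))
    settings <- list(lambda = lambda)
  } else {
    if (is.null(c_alpha)) {
      c_alpha <- mr_critical_value(alpha = alpha, m = m, n_sim = n_sim,
                                   seed = seed)
    }
    ps <- sort(p)
    Fhat <- seq_len(m) / m
    keep <- ps < 1
    vals <- (Fhat[keep] - ps[keep] -
               c_alpha * sqrt(ps[keep] * (1 - ps[keep]))) / (1 - ps[keep])
    if (length(vals) == 0L) vals <- 0
    p0 <- 1 - max(vals)
    settings <- list(alpha = alpha, c_alpha = c_alpha, n_sim = n_sim,
                     seed = seed)
  }
  if (clip) p0 <- min(p0, 1)
  p0 <- max(p0, 0)
  structure(list(p0 = p0, method = method, settings = settings),
            class = "p0_estimate")
}

#' @export
print.p0_estimate <- function(x, ...) {
  cat(sprintf("p0 estimate (%s): %.4f\n", x$method, x$p0))
  invisible(x)
}

#' q-values from the positive false discovery rate estimator
#'
#' At p-value threshold t the pFDR is estimated as
#' `p0 * m * t / #\{p_i <= t\}`. Evaluating at each observed p-value and
#' enforcing monotonicity by a running minimum from the largest p-value down
#' gives per-probe q-values that increase in the same order as the
#' p-values; tied p-values receive equal q-values.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param p0 Proportion of true nulls used in the numerator (default 1; pass
#'   an [estimate_p0()] value to sharpen).
#' @return A data frame of class `qvalue_table` with columns `p`, `q` in the
#'   input order; attributes `p0` and `m`.
#' @export
qvalues <- function(p_values, p0 = 1) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    mvp_stop("p-values must lie in (0, 1]")
  }
  if (inherits(p0, "p0_estimate")) p0 <- p0$p0
  if (!is.numeric(p0) || length(p0) != 1L || p0 < 0) {
    mvp_stop("'p0' must be a single non-negative number")
  }
  m <- length(p)
  ord <- order(p)
  raw <- p0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(raw)))
  q <- numeric(m)
  q[ord] <- q_sorted
  out <- data.frame(p = p, q = q)
  attr(out, "p0") <- p0
  attr(out, "m") <- m
  class(out) <- c("qvalue_table", "data.frame")
  out
}

#' Count significant probes across q-value thresholds
#'
#' @param q A [qvalues()] table.
#' @param thresholds Numeric vector of thresholds in (0, 1].
#' @return Data frame with columns `threshold` and `n_significant`,
#'   non-decreasing in `threshold`.
#' @export
significance_curve <- function(q, thresholds) {
  stopifnot(inherits(q, "qvalue_table"))
  if (any(thresholds <= 0) || any(thresholds > 1)) {
    mvp_stop("thresholds must lie in (0, 1]")
  }
  data.frame(
    threshold = thresholds,
    n_significant = vapply(thresholds, function(t) sum(q$q <= t), integer(1L))
  )
}

#' Bonferroni-adjusted significance threshold
#'
#' Family-wise error control at level `alpha` over `m` tests uses the
#' per-test threshold `alpha / m`; filtering probes (smaller m) makes the
#' threshold more liberal and increases power.
#'
#' @param alpha Significance level in (0, 1].
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    mvp_stop("'alpha' must be in (0, 1]")
  }
  m <- stopifnot_scalar_count(m, "m")
  alpha / m
}
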