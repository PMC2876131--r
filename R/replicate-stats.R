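# Replicate concordance statistics. The probe correlation (Pearson, across
# biosamples, between a probe's two technical replicates) estimates
# VAR(A) / (VAR(A) + VAR(E)): the share of a probe's variance that is
# biological rather than measurement error. The sample correlation (across
# probes, within a replicate pair) estimates VAR(M) / (VAR(M) + VAR(E)) and
# is the companion diagnostic that separates "large error" from "little
# biological variation" as explanations for low probe correlations.

# Row-wise Pearson correlation between two equally shaped matrices using
# pairwise-complete observations; returns r, n used, and degeneracy flags.
row_pearson <- function(x, y) {
  m <- !is.na(x) & !is.na(y)
  xm <- ifelse(m, x, 0)
  ym <- ifelse(m, y, 0)
  n <- rowSums(m)
  sx <- rowSums(xm); sy <- rowSums(ym)
  sxx <- rowSums(xm * xm); syy <- rowSums(ym * ym); sxy <- rowSums(xm * ym)
  cov <- sxy - sx * sy / n
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  scale <- pmax(sxx, syy, 1e-300)
  degenerate <- (vx <= 1e-12 * scale) | (vy <= 1e-12 * scale)
  r <- ifelse(n >= 2 & !degenerate, cov / sqrt(pmax(vx, 0) * pmax(vy, 0)),
              NA_real_)
  r <- pmin(pmax(r, -1), 1)
  list(r = r, n = n, degenerate = degenerate)
}

#' Per-probe technical-replicate correlations
#'
#' For every probe, the Pearson correlation between its replicate-1 and
#' replicate-2 measurements across the paired biosamples, over
#' pairwise-complete pairs. The correlation is flagged undefined when fewer
#' than `min_pairs` complete pairs remain or either replicate vector has
#' zero variance; such probes are by definition non-variable and downstream
#' selection treats them as such. Also reports each probe's total variance
#' (variance across biosamples of the per-biosample replicate-mean beta) and
#' mean methylation.
#'
#' @param betas A [beta_matrix()].
#' @param design A [replicate_design()]; every design sample must be a
#'   column of `betas`.
#' @param min_pairs Minimum complete pairs for a defined correlation
#'   (default 10, at least 3).
#' @return A data frame of class `probe_correlations` with columns
#'   `probe_id`, `r`, `n_pairs`, `total_var`, `mean_meth`, `defined`.
#' @export
probe_correlations <- function(betas, design, min_pairs = 10L) {
  stopifnot(inherits(betas, "beta_matrix"), inherits(design, "replicate_design"))
  min_pairs <- stopifnot_scalar_count(min_pairs, "min_pairs")
  if (min_pairs < 3L) mvp_stop("'min_pairs' must be >= 3")
  check_design_samples(betas, design)

  rep1 <- unclass(betas)[, as.character(design$sample_rep1), drop = FALSE]
  rep2 <- unclass(betas)[, as.character(design$sample_rep2), drop = FALSE]
  pc <- row_pearson(rep1, rep2)
  defined <- !is.na(pc$r) & pc$n >= min_pairs
  r <- ifelse(defined, pc$r, NA_real_)

  # total variance across biosamples of replicate-mean betas: replicate pairs
  # are averaged first, unpaired samples enter singly
  paired_cols <- c(as.character(design$sample_rep1),
                   as.character(design$sample_rep2))
  single_cols <- setdiff(colnames(betas), paired_cols)
  pair_means <- (rep1 + rep2) / 2
  only1 <- is.na(rep2) & !is.na(rep1)
  only2 <- is.na(rep1) & !is.na(rep2)
  pair_means[only1] <- rep1[only1]
  pair_means[only2] <- rep2[only2]
  biosample_means <- cbind(pair_means,
                           unclass(betas)[, single_cols, drop = FALSE])
  n_obs <- rowSums(!is.na(biosample_means))
  mu <- rowMeans(biosample_means, na.rm = TRUE)
  total_var <- rowSums((biosample_means - mu)^2, na.rm = TRUE) /
    pmax(n_obs - 1L, 1L)
  total_var[n_obs < 2L] <- NA_real_

  out <- data.frame(
    probe_id = rownames(betas),
    r = r,
    n_pairs = as.integer(pc$n),
    total_var = total_var,
    mean_meth = rowMeans(unclass(betas), na.rm = TRUE),
    defined = defined,
    stringsAsFactors = FALSE
  )
  class(out) <- c("probe_correlations", "data.frame")
  out
}

#' Per-pair sample correlations
#'
#' For every technical-replicate pair, the Pearson correlation between the
#' two replicate profiles across all probes with both values observed.
#'
#' @inheritParams probe_correlations
#' @return A data frame of class `sample_correlations` with columns
#'   `pair_id`, `r`, `n_probes`, `defined`.
#' @export
sample_correlations <- function(betas, design) {
  stopifnot(inherits(betas, "beta_matrix"), inherits(design, "replicate_design"))
  check_design_samples(betas, design)
  rep1 <- unclass(betas)[, as.character(design$sample_rep1), drop = FALSE]
  rep2 <- unclass(betas)[, as.character(design$sample_rep2), drop = FALSE]
  pc <- row_pearson(t(rep1), t(rep2))
  defined <- !is.na(pc$r) & pc$n >= 3L
  out <- data.frame(
    pair_id = design$pair_id,
    r = ifelse(defined, pc$r, NA_real_),
    n_probes = as.integer(pc$n),
    defined = defined,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_correlations", "data.frame")
  out
}

check_design_samples <- function(betas, design) {
  ids <- c(as.character(design$sample_rep1), as.character(design$sample_rep2))
  missing <- setdiff(ids, colnames(betas))
  if (length(missing) > 0L) {
    mvp_stop(sprintf("design samples absent from beta matrix: %s",
                     paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Replicate-concordance diagnostics
#'
#' Summaries used to attribute low probe correlations to low biological
#' variance rather than high measurement error: the correlation of the probe
#' correlations with total probe variance (positive when low correlations
#' reflect low biological variation) and with mean methylation level, plus
#' means and SDs of both correlation sets.
#'
#' @param pct A [probe_correlations()] table.
#' @param sct A [sample_correlations()] table.
#' @return A list of class `replicate_diagnostics`.
#' @export
diagnostics <- function(pct, sct) {
  stopifnot(inherits(pct, "probe_correlations"),
            inherits(sct, "sample_correlations"))
  ok <- pct$defined
  if (sum(ok) < 3L) {
    mvp_stop("need at least 3 probes with defined correlations")
  }
  if (sum(ok) < 10L) {
    warning("fewer than 10 defined probe correlations: diagnostics unstable")
  }
  out <- list(
    corr_probecorr_totalvar = stats::cor(pct$r[ok], pct$total_var[ok]),
    corr_probecorr_meanmeth = stats::cor(pct$r[ok], pct$mean_meth[ok]),
    mean_probe_correlation = mean(pct$r[ok]),
    sd_probe_correlation = stats::sd(pct$r[ok]),
    mean_sample_correlation = mean(sct$r[sct$defined]),
    sd_sample_correlation = stats::sd(sct$r[sct$defined]),
    n_probes_used = sum(ok),
    n_pairs_used = sum(sct$defined)
  )
  class(out) <- "replicate_diagnostics"
  out
}

#' @export
print.replicate_diagnostics <- function(x, ...) {
  cat("Replicate concordance diagnostics\n")
  cat(sprintf("  probe correlations : mean %.3f (SD %.3f) over %d probes\n",
              x$mean_probe_correlation, x$sd_probe_correlation,
              x$n_probes_used))
  cat(sprintf("  sample correlations: mean %.4f (SD %.4f) over %d pairs\n",
              x$mean_sample_correlation, x$sd_sample_correlation,
              x$n_pairs_used))
  cat(sprintf("  cor(probe r, total variance): %.3f\n",
              x$corr_probecorr_totalvar))
  cat(sprintf("  cor(probe r, mean methylation): %.3f\n",
              x$corr_probecorr_meanmeth))
  invisible(x)
}

#' Expected replicate correlation for a signal-to-error variance ratio
#'
#' With biological variance `VAR(A) = lambda * VAR(E)`, the population
#' correlation between two technical replicates is
#' `lambda / (1 + lambda)`.
#'
#' @param lambda_ratio Non-negative ratio `VAR(A) / VAR(E)`.
#' @return The expected Pearson correlation, in `[0, 1)`.
#' @export
expected_correlation <- function(lambda_ratio) {
  if (any(!is.finite(lambda_ratio)) || any(lambda_ratio < 0)) {
    mvp_stop("'lambda_ratio' must be finite and >= 0")
  }
  lambda_ratio / (1 + lambda_ratio)
}
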