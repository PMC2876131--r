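# Two-channel signal preprocessing: background correction, optional
# bisulfite-conversion adjustment, and conversion of Cy3/Cy5 intensities to
# beta values.

#' Background- and conversion-correct two-channel signals
#'
#' For each sample and channel the background is estimated as the mean of
#' that sample's negative-control intensities when a controls table supplies
#' them, and as the 5th percentile of the sample's intensities in that
#' channel otherwise. Corrected intensities are floored at `alpha_floor`
#' after background subtraction. When per-sample bisulfite conversion scores
#' are available, a per-channel ordinary least squares regression of the
#' per-sample mean log corrected intensity on the conversion score is fitted
#' across samples, and each sample's fitted deviation from the grand mean is
#' removed from its log intensities. Both corrections operate on each
#' channel independently.
#'
#' This correction is an approximation of the unpublished vendor-level
#' procedure and is flagged as such in the report; users with precomputed
#' beta values can bypass it entirely.
#'
#' @param signals A [signal_table()].
#' @param controls Optional data frame with `sample_id` and any of
#'   `conversion_score`, `background_cy3`, `background_cy5`.
#' @param alpha_floor Minimum corrected intensity (intensity units,
#'   default 1), preventing zero or negative values entering the beta ratio.
#' @return A list with elements `signals` (corrected `signal_table`) and
#'   `report` (per sample/channel background estimates, conversion
#'   regression slopes, and counts of floored values).
#' @export
correct_signals <- function(signals, controls = NULL, alpha_floor = 1) {
  stopifnot(inherits(signals, "signal_table"))
  if (nrow(signals) == 0L) mvp_stop("signal table is empty")
  if (!is.numeric(alpha_floor) || length(alpha_floor) != 1L ||
      !is.finite(alpha_floor) || alpha_floor <= 0) {
    mvp_stop("'alpha_floor' must be a single positive number")
  }
  samples <- unique(signals$sample_id)
  report <- list(alpha_floor = alpha_floor, background = NULL,
                 conversion = NULL, approximate = TRUE)

  bg_rows <- list()
  for (ch in c("cy3", "cy5")) {
    ctrl_col <- paste0("background_", ch)
    per_sample_bg <- vapply(samples, function(s) {
      if (!is.null(controls) && ctrl_col %in% names(controls)) {
        v <- controls[[ctrl_col]][match(s, controls$sample_id)]
        if (length(v) == 1L && !is.na(v)) return(as.numeric(v))
      }
      stats::quantile(signals[[ch]][signals$sample_id == s], probs = 0.05,
                      names = FALSE, type = 7)
    }, numeric(1L))
    if (any(per_sample_bg < 0)) mvp_stop("background estimates must be >= 0")
    raw <- signals[[ch]]
    bg <- per_sample_bg[match(signals$sample_id, samples)]
    corrected <- pmax(raw - bg, alpha_floor)
    n_floored <- sum(raw - bg < alpha_floor)
    signals[[ch]] <- corrected
    bg_rows[[ch]] <- data.frame(sample_id = samples, channel = ch,
                                background = unname(per_sample_bg),
                                stringsAsFactors = FALSE)
    report$n_floored[[ch]] <- n_floored
  }
  report$background <- do.call(rbind, bg_rows)

  scores <- NULL
  if (!is.null(controls) && "conversion_score" %in% names(controls)) {
    scores <- controls$conversion_score[match(samples, controls$sample_id)]
  }
  if (!is.null(scores) && any(!is.na(scores))) {
    ok <- !is.na(scores)
    if (sum(ok) < 3L) {
      mvp_stop("conversion correction needs at least 3 samples with scores")
    }
    conv_rows <- list()
    for (ch in c("cy3", "cy5")) {
      logv <- log(signals[[ch]])
      sample_mean <- vapply(samples, function(s) {
        mean(logv[signals$sample_id == s])
      }, numeric(1L))
      fit <- stats::lm(sample_mean[ok] ~ scores[ok])
      slope <- unname(stats::coef(fit)[2L])
      fitted_all <- unname(stats::coef(fit)[1L]) + slope * scores
      deviation <- fitted_all - mean(sample_mean[ok])
      deviation[is.na(deviation)] <- 0
      adj <- logv - deviation[match(signals$sample_id, samples)]
      signals[[ch]] <- exp(adj)
      conv_rows[[ch]] <- data.frame(channel = ch, slope = slope,
                                    stringsAsFactors = FALSE)
    }
    report$conversion <- do.call(rbind, conv_rows)
  } else {
    report$conversion_skipped <- TRUE
  }
  list(signals = signal_table(as.data.frame(signals)), report = report)
}

#' Compute beta values from two-channel signals
#'
#' The methylation fraction is the methylated-channel intensity over total
#' intensity, `beta = cy5 / (cy5 + cy3)`. Records with zero total intensity
#' become missing values. The result is invariant to rescaling both channels
#' of a record by any positive constant.
#'
#' @param signals A [signal_table()].
#' @return A [beta_matrix()] (probes x samples).
#' @export
compute_beta <- function(signals) {
  stopifnot(inherits(signals, "signal_table"))
  total <- signals$cy5 + signals$cy3
  beta <- ifelse(total > 0, signals$cy5 / total, NA_real_)
  probes <- unique(as.character(signals$probe_id))
  samples <- unique(as.character(signals$sample_id))
  mat <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
                dimnames = list(probes, samples))
  mat[cbind(match(as.character(signals$probe_id), probes),
            match(as.character(signals$sample_id), samples))] <- beta
  beta_matrix(mat)
}
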