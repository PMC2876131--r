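# Variance-components simulator of replicated methylation array data.
# Signal model: y_ijk = m_j + a_ij + e_ijk, with m_j the probe's average
# methylation, a_ij the biosample-specific deviation (biological signal,
# variance lambda_j * sigma_e^2) and e_ijk independent measurement error
# (variance sigma_e^2) per replicate. Probes belong to one of two latent
# classes — non-variable (lambda_null) or variable (lambda_var) — so the
# expected replicate correlation per class is lambda / (1 + lambda).

#' Simulation configuration
#'
#' Defaults describe a 1505-probe array measured on 311 biosamples with 126
#' technical-replicate pairs: 58% of probes are non-variable with
#' signal-to-error ratio `lambda_null = 0.099` (expected replicate
#' correlation 0.09), the rest variable with `lambda_var = 1.041` (expected
#' correlation 0.51); measurement error SD is 0.02 beta units and per-probe
#' baseline methylation follows a bimodal distribution (60% near 0.15, 40%
#' near 0.75, truncated to [0.02, 0.98]) typical of CpG panels.
#'
#' @param n_probes,n_samples,n_replicate_pairs Dataset dimensions.
#' @param pi_null Proportion of non-variable probes.
#' @param sigma_e Measurement error SD (beta units).
#' @param lambda_null,lambda_var Biological-to-error variance ratios
#'   `VAR(A)/VAR(E)` for the two probe classes.
#' @param mean_weights,mean_locations,mean_sds Mixture describing the
#'   per-probe baseline methylation distribution.
#' @param mean_bounds Truncation interval for baseline methylation.
#' @param clip If `TRUE` (default) clip simulated betas to `[0, 1]`.
#' @param shuffle_pairs If `TRUE`, pick replicate pairs at random instead of
#'   the first `n_replicate_pairs` samples.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_probes = 1505L, n_samples = 311L,
                              n_replicate_pairs = 126L, pi_null = 0.58,
                              sigma_e = 0.02, lambda_null = 0.099,
                              lambda_var = 1.041,
                              mean_weights = c(0.6, 0.4),
                              mean_locations = c(0.15, 0.75),
                              mean_sds = c(0.05, 0.08),
                              mean_bounds = c(0.02, 0.98),
                              clip = TRUE, shuffle_pairs = FALSE,
                              seed = 1L) {
  cfg <- list(
    n_probes = stopifnot_scalar_count(n_probes, "n_probes"),
    n_samples = stopifnot_scalar_count(n_samples, "n_samples"),
    n_replicate_pairs = stopifnot_scalar_count(n_replicate_pairs,
                                               "n_replicate_pairs"),
    pi_null = pi_null, sigma_e = sigma_e, lambda_null = lambda_null,
    lambda_var = lambda_var, mean_weights = mean_weights,
    mean_locations = mean_locations, mean_sds = mean_sds,
    mean_bounds = mean_bounds, clip = isTRUE(clip),
    shuffle_pairs = isTRUE(shuffle_pairs),
    seed = stopifnot_scalar_count(seed, "seed", positive = FALSE)
  )
  if (cfg$n_replicate_pairs > cfg$n_samples) {
    mvp_stop("n_replicate_pairs cannot exceed n_samples")
  }
  if (pi_null < 0 || pi_null > 1) mvp_stop("pi_null must be in [0, 1]")
  if (!is.numeric(sigma_e) || sigma_e <= 0) mvp_stop("sigma_e must be > 0")
  if (lambda_null < 0 || lambda_var < 0) mvp_stop("lambdas must be >= 0")
  if (length(mean_weights) != length(mean_locations) ||
      length(mean_weights) != length(mean_sds)) {
    mvp_stop("baseline-methylation mixture fields must have equal length")
  }
  if (abs(sum(mean_weights) - 1) > 1e-8) {
    mvp_stop("mean_weights must sum to 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Truncated-mixture draw of per-probe baseline methylation, by rejection.
draw_probe_means <- function(n, cfg) {
  out <- numeric(0L)
  while (length(out) < n) {
    k <- sample.int(length(cfg$mean_weights), n, replace = TRUE,
                    prob = cfg$mean_weights)
    m <- stats::rnorm(n, cfg$mean_locations[k], cfg$mean_sds[k])
    m <- m[m >= cfg$mean_bounds[1L] & m <= cfg$mean_bounds[2L]]
    out <- c(out, m)
  }
  out[seq_len(n)]
}

#' Generate a replicated methylation dataset with known truth
#'
#' Realizes the variance-components signal model for the configured probe
#' and sample counts. The paired samples receive two replicates; the
#' replicate-2 columns carry a `_r2` suffix and are recorded in the
#' returned design. Output is fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `betas` ([beta_matrix()]), `design`
#'   ([replicate_design()]) and `truth` — a data frame of class `sim_truth`
#'   with per-probe `class`, `lambda`, `var_a`, `expected_r`, `m`, plus
#'   attributes `sigma_e`, `seed`, `config`, `clipped_fraction` (share of
#'   values affected by clipping) and the latent biological deviations `a`
#'   (probes x base samples).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    np <- cfg$n_probes; ns <- cfg$n_samples; npair <- cfg$n_replicate_pairs
    wid <- max(3L, nchar(as.character(ns)))
    sample_ids <- sprintf(paste0("S%0", wid, "d"), seq_len(ns))
    probe_ids <- sprintf(paste0("cg%0", max(4L, nchar(as.character(np))), "d"),
                         seq_len(np))

    m_j <- draw_probe_means(np, cfg)
    is_null <- stats::runif(np) < cfg$pi_null
    lambda_j <- ifelse(is_null, cfg$lambda_null, cfg$lambda_var)
    var_a <- lambda_j * cfg$sigma_e^2

    a <- matrix(stats::rnorm(np * ns), nrow = np) * sqrt(var_a)
    e1 <- matrix(stats::rnorm(np * ns, sd = cfg$sigma_e), nrow = np)
    y1 <- m_j + a + e1

    pair_idx <- if (cfg$shuffle_pairs) sort(sample.int(ns, npair)) else
      seq_len(npair)
    e2 <- matrix(stats::rnorm(np * npair, sd = cfg$sigma_e), nrow = np)
    y2 <- m_j + a[, pair_idx, drop = FALSE] + e2

    clipped_fraction <- (sum(y1 < 0 | y1 > 1) + sum(y2 < 0 | y2 > 1)) /
      (length(y1) + length(y2))
    if (cfg$clip) {
      y1 <- pmin(pmax(y1, 0), 1)
      y2 <- pmin(pmax(y2, 0), 1)
    }
    rep2_ids <- paste0(sample_ids[pair_idx], "_r2")
    mat <- cbind(y1, y2)
    dimnames(mat) <- list(probe_ids, c(sample_ids, rep2_ids))
    # with clipping off the raw signals may stray outside [0,1]; they are
    # returned on the raw scale without the range validation
    betas <- if (cfg$clip) beta_matrix(mat) else
      structure(mat, class = c("beta_matrix", "matrix", "array"))
    design <- replicate_design(data.frame(
      pair_id = sprintf("P%03d", seq_len(npair)),
      sample_rep1 = sample_ids[pair_idx],
      sample_rep2 = rep2_ids,
      stringsAsFactors = FALSE
    ))
    truth <- data.frame(
      probe_id = probe_ids,
      class = ifelse(is_null, "null", "variable"),
      lambda = lambda_j,
      var_a = var_a,
      expected_r = lambda_j / (1 + lambda_j),
      m = m_j,
      stringsAsFactors = FALSE
    )
    dimnames(a) <- list(probe_ids, sample_ids)
    attr(truth, "a") <- a
    attr(truth, "clipped_fraction") <- clipped_fraction
    attr(truth, "sigma_e") <- cfg$sigma_e
    attr(truth, "seed") <- cfg$seed
    attr(truth, "config") <- cfg
    class(truth) <- c("sim_truth", "data.frame")
    list(betas = betas, design = design, truth = truth)
  })
}

#' Analytic expected sample correlation under a configuration
#'
#' By the law of total variance, the between-probe methylation variance
#' within one biosample is the variance of the baseline mixture plus the
#' average biological variance; the expected sample correlation is that
#' variance over itself plus the error variance. Truncation of the baseline
#' distribution is ignored (it is slight under the defaults).
#'
#' @param config A [simulation_config()].
#' @return Expected sample correlation (scalar).
#' @export
expected_sample_correlation <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$mean_weights; mu <- config$mean_locations; s <- config$mean_sds
  grand <- sum(w * mu)
  var_m <- sum(w * (s^2 + mu^2)) - grand^2
  mean_var_a <- (config$pi_null * config$lambda_null +
                   (1 - config$pi_null) * config$lambda_var) * config$sigma_e^2
  var_profile <- var_m + mean_var_a
  var_profile / (var_profile + config$sigma_e^2)
}

#' Simulate probe-linked continuous outcomes
#'
#' Builds an outcome as a weighted sum of standardized latent biological
#' deviations of `n_causal` probes plus standard normal noise, so true
#' associations exist only where the simulation placed biological signal.
#' With `restrict_to_variable = TRUE` the causal probes are drawn from the
#' variable class only.
#'
#' @param truth A `sim_truth` from [generate_dataset()].
#' @param n_causal Number of causal probes (may be 0).
#' @param effect_size Effect per causal probe, in outcome-SD units per SD of
#'   biological deviation (default 0.4).
#' @param restrict_to_variable Sample causal probes from the variable class
#'   only (default `TRUE`).
#' @param seed Seed for causal-probe sampling and outcome noise.
#' @param outcome_name Column name for the outcome.
#' @return An [outcome_table()] for the base (non-suffixed) samples, with
#'   attribute `causal_ids`.
#' @export
generate_outcomes <- function(truth, n_causal = 10L, effect_size = 0.4,
                              restrict_to_variable = TRUE, seed = 1L,
                              outcome_name = "outcome") {
  stopifnot(inherits(truth, "sim_truth"))
  n_causal <- as.integer(n_causal)
  if (n_causal < 0L) mvp_stop("'n_causal' must be >= 0")
  a <- attr(truth, "a")
  eligible <- if (restrict_to_variable) {
    truth$probe_id[truth$class == "variable"]
  } else truth$probe_id
  if (restrict_to_variable && length(eligible) == 0L) {
    mvp_stop("no variable-class probes to draw causal probes from")
  }
  if (n_causal > length(eligible)) {
    mvp_stop("'n_causal' exceeds the number of eligible probes")
  }
  ns <- ncol(a)
  out <- with_seed(seed, {
    causal <- if (n_causal > 0L) sample(eligible, n_causal) else character(0L)
    y <- stats::rnorm(ns)
    for (pid in causal) {
      v <- a[pid, ]
      s <- stats::sd(v)
      if (s > 0) y <- y + effect_size * (v - mean(v)) / s
    }
    list(y = y, causal = causal)
  })
  tab <- outcome_table(data.frame(sample_id = colnames(a),
                                  out$y, stringsAsFactors = FALSE))
  names(tab)[2L] <- outcome_name
  attr(tab, "causal_ids") <- out$causal
  tab
}
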