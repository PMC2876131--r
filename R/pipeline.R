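# End-to-end pipeline and the command-line front end. The CLI is a thin
# dispatcher over exported functions: simulate / betas / correlate / fit /
# select / associate / run-all, all randomness flowing from one --seed.

#' Run the full simulate-to-associate workflow
#'
#' Generates a replicated dataset, computes replicate correlations, fits the
#' mixture, selects variable probes, simulates a probe-linked outcome, and
#' runs the association scan before and after selection. All stage outputs
#' are written to `out_dir` along with a JSON manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for every stage.
#' @param config A [simulation_config()]; its seed is overridden by `seed`.
#' @param K,threshold Mixture size and posterior selection cutoff.
#' @param n_causal,effect_size Outcome simulation settings.
#' @param verbose Print stage progress.
#' @return A list of class `run_manifest` (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(out_dir, seed = 17L,
                         config = simulation_config(),
                         K = 2L, threshold = 0.5, n_causal = 10L,
                         effect_size = 0.4, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  config$seed <- stopifnot_scalar_count(seed, "seed", positive = FALSE)
  outputs <- character(0L)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    outputs <<- c(outputs, path)
    path
  }

  say("stage simulate: %d probes, %d samples, %d pairs",
      config$n_probes, config$n_samples, config$n_replicate_pairs)
  sim <- generate_dataset(config)
  write_beta_matrix(sim$betas, emit("betas.tsv"))
  write_tsv(as.data.frame(sim$design), emit("design.tsv"))
  write_tsv(as.data.frame(sim$truth), emit("truth.tsv"))
  outc <- generate_outcomes(sim$truth, n_causal = n_causal,
                            effect_size = effect_size, seed = seed)
  write_tsv(as.data.frame(outc), emit("outcomes.tsv"))

  say("stage correlate")
  pct <- probe_correlations(sim$betas, sim$design)
  sct <- sample_correlations(sim$betas, sim$design)
  write_tsv(data.frame(probe_id = pct$probe_id, r = pct$r,
                       n_pairs = pct$n_pairs, total_var = pct$total_var,
                       mean_meth = pct$mean_meth),
            emit("probecorr.tsv"))
  write_tsv(data.frame(pair_id = sct$pair_id, r = sct$r,
                       n_probes = sct$n_probes),
            emit("samplecorr.tsv"))
  say("  %d probes read, %d pairs used", nrow(pct), nrow(sct))

  say("stage fit: K = %d", K)
  model <- fit_mixture(pct$r[pct$defined], K = K, seed = seed)
  write_mixture_json(model, emit("model.json"))

  say("stage select: threshold %.3g", threshold)
  post <- posteriors(model, pct)
  sel <- select_probes(post, threshold = threshold)
  say("  %d probes selected", sel$n_selected)
  write_tsv(data.frame(probe_id = post$probe_id,
                       posterior_variable = 1 - post$class1,
                       selected = unname(sel$mask)),
            emit("selection.tsv"))

  say("stage associate")
  before <- association_scan(sim$betas, outc)
  after <- association_scan(sim$betas, outc, selection = sel)
  p0_before <- estimate_p0(before$p, seed = seed)
  p0_after <- estimate_p0(after$p, seed = seed)
  qb <- qvalues(before$p)
  qa <- qvalues(after$p)
  write_tsv(data.frame(probe_id = before$probe_id, F = before$F,
                       p = before$p, q = qb$q), emit("assoc_before.tsv"))
  write_tsv(data.frame(probe_id = after$probe_id, F = after$F,
                       p = after$p, q = qa$q), emit("assoc_after.tsv"))
  jsonlite::write_json(
    list(p0_before = p0_before$p0, p0_after = p0_after$p0,
         n_selected = sel$n_selected),
    emit("summary.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    tool = "mvpfilter",
    version = as.character(utils::packageVersion("mvpfilter")),
    command = "run-all",
    seed = seed,
    parameters = list(K = K, threshold = threshold, n_causal = n_causal,
                      effect_size = effect_size,
                      n_probes = config$n_probes,
                      n_samples = config$n_samples,
                      n_replicate_pairs = config$n_replicate_pairs),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$outputs <- c(manifest$outputs, file.path(out_dir, "manifest.json"))
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

# --- minimal flag parser: --name value pairs plus switches ---------------
parse_cli_args <- function(args, switches = character(0L)) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) mvp_stop(sprintf("unexpected argument: %s", a))
    nm <- sub("^--", "", a)
    if (nm %in% switches) {
      out[[nm]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) mvp_stop(sprintf("flag --%s needs a value", nm))
      out[[nm]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

cli_get <- function(opts, name, default = NULL, required = FALSE) {
  if (!is.null(opts[[name]])) return(opts[[name]])
  if (required) mvp_stop(sprintf("missing required flag --%s", name))
  default
}

#' Command-line interface dispatcher
#'
#' Implements the subcommands `simulate`, `betas`, `correlate`, `fit`,
#' `select`, `associate` and `run-all`. Intended to be invoked through the
#' `mvpfilter` script (in `inst/scripts/`), which maps error classes to
#' exit codes: missing input 2, validation failure 3, numeric failure 4.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result object of the subcommand.
#' @export
mvp_cli <- function(args) {
  if (length(args) == 0L) {
    mvp_stop(paste("usage: mvpfilter <simulate|betas|correlate|fit|select|",
                   "associate|run-all> [flags]"))
  }
  cmd <- args[1L]
  opts <- parse_cli_args(args[-1L],
                         switches = c("no-correction", "verbose"))
  seed <- as.integer(cli_get(opts, "seed", 1L))
  verbose <- isTRUE(opts[["verbose"]])

  result <- switch(
    cmd,
    "simulate" = {
      out_dir <- cli_get(opts, "out-dir", required = TRUE)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      cfg <- simulation_config(seed = seed)
      sim <- generate_dataset(cfg)
      write_beta_matrix(sim$betas, file.path(out_dir, "betas.tsv"))
      write_tsv(as.data.frame(sim$design), file.path(out_dir, "design.tsv"))
      write_tsv(as.data.frame(sim$truth), file.path(out_dir, "truth.tsv"))
      sim
    },
    "betas" = {
      signals <- read_signal_table(cli_get(opts, "signals", required = TRUE))
      ctrl_path <- cli_get(opts, "controls")
      controls <- if (!is.null(ctrl_path)) read_signal_controls(ctrl_path)
      if (!isTRUE(opts[["no-correction"]])) {
        signals <- correct_signals(signals, controls)$signals
      }
      betas <- compute_beta(signals)
      write_beta_matrix(betas, cli_get(opts, "out", required = TRUE))
      betas
    },
    "correlate" = {
      betas <- read_beta_matrix(cli_get(opts, "betas", required = TRUE))
      design <- read_replicate_design(cli_get(opts, "design", required = TRUE))
      pct <- probe_correlations(betas, design)
      sct <- sample_correlations(betas, design)
      write_tsv(data.frame(probe_id = pct$probe_id, r = pct$r,
                           n_pairs = pct$n_pairs, total_var = pct$total_var,
                           mean_meth = pct$mean_meth),
                cli_get(opts, "out", required = TRUE))
      out_samples <- cli_get(opts, "out-samples")
      if (!is.null(out_samples)) {
        write_tsv(data.frame(pair_id = sct$pair_id, r = sct$r,
                             n_probes = sct$n_probes), out_samples)
      }
      list(probes = pct, samples = sct)
    },
    "fit" = {
      pct <- utils::read.delim(cli_get(opts, "correlations", required = TRUE))
      model <- fit_mixture(pct$r,
                           K = as.integer(cli_get(opts, "k", 2L)),
                           n_restarts = as.integer(cli_get(opts, "restarts", 10L)),
                           seed = seed)
      write_mixture_json(model, cli_get(opts, "out", required = TRUE))
      model
    },
    "select" = {
      model <- read_mixture_json(cli_get(opts, "model", required = TRUE))
      raw <- utils::read.delim(cli_get(opts, "correlations", required = TRUE))
      pct <- data.frame(probe_id = raw$probe_id, r = raw$r,
                        defined = !is.na(raw$r), stringsAsFactors = FALSE)
      post <- posteriors(model, pct)
      sel <- select_probes(post,
                           threshold = as.numeric(cli_get(opts, "threshold", 0.5)))
      write_tsv(data.frame(probe_id = post$probe_id,
                           posterior_variable = 1 - post$class1,
                           selected = unname(sel$mask)),
                cli_get(opts, "out", required = TRUE))
      sel
    },
    "associate" = {
      betas <- read_beta_matrix(cli_get(opts, "betas", required = TRUE))
      outcomes <- read_outcomes(cli_get(opts, "outcomes", required = TRUE))
      outcome <- cli_get(opts, "outcome-name")
      sel_path <- cli_get(opts, "selection")
      selection <- NULL
      if (!is.null(sel_path)) {
        if (!file.exists(sel_path)) mvp_missing_input(sel_path)
        st <- utils::read.delim(sel_path)
        mask <- as.logical(st$selected)
        names(mask) <- st$probe_id
        selection <- structure(list(threshold = NA_real_,
                                    selected = st$probe_id[mask],
                                    n_selected = sum(mask),
                                    n_excluded = sum(!mask), mask = mask),
                               class = "mvp_selection")
      }
      assoc <- association_scan(betas, outcomes, outcome = outcome,
                                selection = selection)
      p0 <- estimate_p0(assoc$p,
                        method = cli_get(opts, "p0-method", "meinshausen-rice"),
                        seed = seed)
      q <- qvalues(assoc$p)
      write_tsv(data.frame(probe_id = assoc$probe_id, F = assoc$F,
                           p = assoc$p, q = q$q),
                cli_get(opts, "out", required = TRUE))
      list(associations = assoc, p0 = p0)
    },
    "run-all" = {
      run_pipeline(cli_get(opts, "out-dir", required = TRUE), seed = seed,
                   verbose = verbose)
    },
    mvp_stop(sprintf("unknown subcommand: %s", cmd))
  )
  invisible(result)
}
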