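# Tabular I/O for the package's artifact formats. All files are
# tab-separated with a header row; missing beta values are empty cells or
# "NA". Numeric output is written at 10 significant digits so that
# read -> write -> read round-trips are exact at that precision.

#' Construct a validated beta-value matrix
#'
#' A beta matrix holds methylation fractions (values in \code{[0, 1]}) with
#' probes as rows and samples as columns. Missing measurements are `NA`.
#'
#' @param values Numeric matrix, probes x samples.
#' @param probe_ids,sample_ids Optional character vectors of unique row and
#'   column identifiers; taken from `dimnames(values)` when omitted.
#' @return A numeric matrix of class `beta_matrix`.
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    mvp_stop("'values' must be a numeric matrix")
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    mvp_stop("probe and sample identifiers are required")
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(probe_ids)) {
    mvp_stop(sprintf("duplicated probe id: %s",
                     probe_ids[duplicated(probe_ids)][1L]),
             class = "mvp_format_error")
  }
  if (anyDuplicated(sample_ids)) {
    mvp_stop(sprintf("duplicated sample id: %s",
                     sample_ids[duplicated(sample_ids)][1L]),
             class = "mvp_format_error")
  }
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids)) {
    mvp_stop("dimensions do not match probe/sample identifiers")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1 | !is.finite(values)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    mvp_stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s'",
      probe_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' Read a beta-value matrix from TSV
#'
#' Expected layout: header `probe_id<TAB>S1<TAB>S2...`, one probe per row.
#' Empty cells and `NA` become missing values.
#'
#' @param path Path to a tab-separated file.
#' @return A `beta_matrix`.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) mvp_missing_input(path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  if (ncol(df) < 2L) {
    mvp_stop(sprintf("'%s': need a probe_id column plus sample columns", path),
             class = "mvp_format_error")
  }
  probe_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    mvp_stop(sprintf("'%s': non-numeric value in data row %d, column '%s'",
                     path, bad[1L, 1L], colnames(vals)[bad[1L, 2L]]),
             class = "mvp_format_error")
  }
  beta_matrix(num, probe_ids = probe_ids, sample_ids = colnames(vals))
}

#' Write a beta-value matrix to TSV
#'
#' @param betas A `beta_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path) {
  stopifnot(inherits(betas, "beta_matrix"))
  out <- apply(unclass(betas), 2L, function(col) {
    ifelse(is.na(col), NA_character_,
           formatC(col, digits = 10L, format = "g"))
  })
  df <- data.frame(probe_id = rownames(betas), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a two-channel signal table from TSV
#'
#' Long format, header `sample_id<TAB>probe_id<TAB>cy3<TAB>cy5`. Cy3 carries
#' the unmethylated-allele and Cy5 the methylated-allele fluorescence.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame of class `signal_table`.
#' @export
read_signal_table <- function(path) {
  if (!file.exists(path)) mvp_missing_input(path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  signal_table(df)
}

#' Construct a validated signal table
#'
#' @param df Data frame with columns `sample_id`, `probe_id`, `cy3`, `cy5`.
#' @return A data frame of class `signal_table`.
#' @export
signal_table <- function(df) {
  need <- c("sample_id", "probe_id", "cy3", "cy5")
  if (!all(need %in% names(df))) {
    mvp_stop(sprintf("signal table must have columns: %s",
                     paste(need, collapse = ", ")),
             class = "mvp_format_error")
  }
  for (ch in c("cy3", "cy5")) {
    v <- df[[ch]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      mvp_stop(sprintf("negative or non-finite %s intensity in row %d", ch,
                       bad[1L]))
    }
  }
  key <- paste(df$sample_id, df$probe_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    mvp_stop(sprintf("duplicate record for sample '%s', probe '%s' (row %d)",
                     df$sample_id[i], df$probe_id[i], i))
  }
  class(df) <- c("signal_table", "data.frame")
  df
}

#' Read a per-sample control sidecar table
#'
#' Header `sample_id<TAB>conversion_score<TAB>background_cy3<TAB>background_cy5`;
#' the background columns are optional.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame.
#' @export
read_signal_controls <- function(path) {
  if (!file.exists(path)) mvp_missing_input(path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    mvp_stop("controls table must have a 'sample_id' column",
             class = "mvp_format_error")
  }
  df
}

#' Construct a validated replicate design
#'
#' Pairs sample identifiers that are technical replicates (the same biosample
#' assayed twice). No sample id may appear in more than one slot.
#'
#' @param df Data frame with columns `pair_id`, `sample_rep1`, `sample_rep2`.
#' @return A data frame of class `replicate_design`.
#' @export
replicate_design <- function(df) {
  need <- c("pair_id", "sample_rep1", "sample_rep2")
  if (!all(need %in% names(df))) {
    mvp_stop(sprintf("replicate design must have columns: %s",
                     paste(need, collapse = ", ")),
             class = "mvp_format_error")
  }
  ids <- c(as.character(df$sample_rep1), as.character(df$sample_rep2))
  if (anyDuplicated(ids)) {
    mvp_stop(sprintf("sample '%s' appears more than once in the design",
                     ids[duplicated(ids)][1L]))
  }
  if (anyDuplicated(df$pair_id)) {
    mvp_stop("duplicated pair_id in replicate design")
  }
  class(df) <- c("replicate_design", "data.frame")
  df
}

#' Read a replicate design from TSV
#'
#' Header `pair_id<TAB>sample_rep1<TAB>sample_rep2`.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame of class `replicate_design`.
#' @export
read_replicate_design <- function(path) {
  if (!file.exists(path)) mvp_missing_input(path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  replicate_design(df)
}

#' Read an outcome table from TSV
#'
#' Header `sample_id<TAB><outcome1><TAB><outcome2>...`; one row per sample,
#' one column per continuous outcome.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame of class `outcome_table`.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) mvp_missing_input(path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  outcome_table(df)
}

#' Construct a validated outcome table
#'
#' @param df Data frame whose first column is `sample_id`; remaining columns
#'   are numeric outcomes (missing values allowed).
#' @return A data frame of class `outcome_table`.
#' @export
outcome_table <- function(df) {
  if (!"sample_id" %in% names(df)) {
    mvp_stop("outcome table must have a 'sample_id' column",
             class = "mvp_format_error")
  }
  if (anyDuplicated(df$sample_id)) {
    mvp_stop("duplicated sample_id in outcome table")
  }
  for (nm in setdiff(names(df), "sample_id")) {
    v <- df[[nm]]
    if (!is.numeric(v)) mvp_stop(sprintf("outcome '%s' is not numeric", nm))
    if (any(is.infinite(v))) {
      mvp_stop(sprintf("outcome '%s' contains non-finite values", nm))
    }
  }
  class(df) <- c("outcome_table", "data.frame")
  df
}

# Generic TSV writer used by the pipeline for result tables.
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(col) {
    ifelse(is.na(col), NA_character_, formatC(col, digits = 10L, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
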