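# Internal helpers: typed error conditions and a local RNG scope.

mvp_stop <- function(msg, class = "mvp_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

mvp_missing_input <- function(path) {
  mvp_stop(sprintf("input file not found: %s", path), class = "mvp_missing_input")
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  # run `code` under a fixed RNG state, restoring the caller's state after
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      (positive && x < 1)) {
    mvp_stop(sprintf("'%s' must be a single positive integer", name))
  }
  as.integer(x)
}
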