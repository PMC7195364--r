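# Internal helpers shared across modules.

#' Signal a validation error
#'
#' All input-validation failures in the package raise a condition of class
#' `agestrat_error`, so that the command-line front end can map them to a
#' non-zero exit status while programming errors propagate unchanged.
#'
#' @param ... Passed to [sprintf()] to build the message.
#' @keywords internal
#' @noRd
stop_agestrat <- function(...) {
  msg <- sprintf(...)
  stop(structure(
    class = c("agestrat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Check that a file exists before parsing it
#' @noRd
check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_agestrat("file not found: %s", as.character(path)[1L])
  }
  invisible(path)
}

#' Roman-numeral age-group labels, oldest = I
#'
#' With `n` rungs the youngest rung (index 1, the focal species) is labelled
#' with the largest numeral, so a 5-rung ladder reads V (youngest) .. I
#' (oldest), the convention used throughout.
#' @noRd
default_rung_labels <- function(n) {
  as.character(utils::as.roman(seq(n, 1L)))
}

#' Run an expression with a private RNG stream
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state, so
#' that seeded helpers (bootstraps, simulators) do not perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
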