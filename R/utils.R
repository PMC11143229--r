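# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All errors raised by the package carry a subclass of the form
#' `snf_error_<what>` so callers can dispatch on the failure mode.
#' @noRd
snf_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(paste0("snf_error_", class), "snf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

snf_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("snf_warning_", class), "snf_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression under a fixed RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Standard error of the mean, sd/sqrt(n)
#' @param x numeric vector
#' @return numeric scalar; `NA` for n < 2
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# numeric equality with relative slack
near <- function(a, b, tol = 1e-8) abs(a - b) <= tol * pmax(1, abs(a), abs(b))
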