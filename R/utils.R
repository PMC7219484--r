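# Physical constants (SI, CODATA 2018)
.FARADAY <- 96485.33212      # C / mol
.GAS_R   <- 8.314462618      # J / (mol K)

#' Run an expression with a fixed RNG seed, restoring global RNG state
#'
#' All stochastic components of the package route their randomness through
#' this helper so that a single integer seed pins the whole pipeline without
#' clobbering the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# consistent error helper: all user-facing errors carry a picostat_error class
stop_picostat <- function(msg, class) {
  stop(structure(class = c(class, "picostat_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Format a current in convenient display units
#'
#' Internal computations are all in amperes; this helper is for printing.
#'
#' @param i_a current in amperes (vectorized).
#' @param digits significant digits.
#' @return character vector like "14.39 uA".
#' @export
format_current <- function(i_a, digits = 4) {
  vapply(i_a, function(x) {
    ax <- abs(x)
    if (!is.finite(x)) return(as.character(x))
    if (ax >= 1 || ax == 0) sprintf("%s A", signif(x, digits))
    else if (ax >= 1e-3) sprintf("%s mA", signif(x * 1e3, digits))
    else if (ax >= 1e-6) sprintf("%s uA", signif(x * 1e6, digits))
    else sprintf("%s nA", signif(x * 1e9, digits))
  }, character(1))
}
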