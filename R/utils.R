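# Internal helpers shared across the package.

# Mass of 1 Da in kg (CODATA).
.DA_TO_KG <- 1.66053906892e-27

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the state on exit, so seeded draws inside the package never
#' disturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("'%s' must be a finite numeric scalar", name)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_invalid("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_scalar(x, name, lower = lower)
  if (x != round(x)) stop_invalid("'%s' must be an integer, got %g", name, x)
  as.integer(x)
}

# Format numerics at 12 significant digits for lossless-enough table output.
format_sig12 <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = 12, format = "g")))
}
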