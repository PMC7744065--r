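# internal validation helpers ------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single finite positive number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stopf("'%s' must be finite and non-negative", name)
  invisible(x)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1)
    stopf("'level' must lie strictly between 0 and 1 (got %s)", format(level))
  invisible(level)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, sets `seed`, evaluates `expr`, and restores
#' the state, so seeded noise generation never disturbs the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("'seed' must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# least squares of y on x returning slope, intercept and RMS residual
ls_line <- function(x, y) {
  fit <- stats::lsfit(x, y)
  res <- fit$residuals
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       residual = sqrt(mean(res^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
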