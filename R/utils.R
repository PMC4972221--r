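# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded package functions never clobber the user's
#' random number stream. A `NULL` seed evaluates `expr` under the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Ezekiel's adjusted R^2; returns NA when the model is saturated.
adjustedR2 <- function(r2, n, p) {
  if (n - p - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# clamp to closed interval
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  }
  invisible(TRUE)
}

# checked coercion of an abundance vector
as_count_vector <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("abundance vector contains missing values", call. = FALSE)
  if (any(x < 0)) stop("abundance vector contains negative counts", call. = FALSE)
  x
}
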