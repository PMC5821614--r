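## Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state so that package functions do not perturb user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-iteration seed derivation: iteration b of a run seeded
## with s uses s + b for its resampling draw and s + b + .seed_offset for the
## embedded ICP fit, so iterations are individually reproducible and
## order-independent. Retry r of a failed iteration shifts by r * .retry_step.
.seed_offset <- 500000L
.retry_step <- 7919L

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) {
    stop(sprintf(
      "'%s' must lie in %s%s, %s%s (got %g)", name,
      if (strict) "(" else "[", lower, upper, if (strict) ")" else "]", x
    ), call. = FALSE)
  }
  invisible(x)
}

## Canonical class labels, used everywhere a label factor is built.
.classes <- c("active", "inactive")

as_activity_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!all(labels %in% .classes)) {
    stop("labels must be 'active' or 'inactive'", call. = FALSE)
  }
  factor(labels, levels = .classes)
}
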