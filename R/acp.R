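#' Aggregated conformal predictor
#'
#' An aggregated conformal predictor (ACP) repeats the inductive conformal
#' procedure over many random proper/calibration splits of the same training
#' data and aggregates the per-class p-values across repetitions by their
#' median. Aggregation stabilises the p-values at the cost of the exact
#' finite-sample guarantee, which empirically still tracks the confidence
#' level closely.
#'
#' `acp()` is deliberately lightweight: it records the training data and
#' configuration; the repeated fits happen inside [predict.acp()] and
#' [internal_validation()], each iteration reproducibly seeded as
#' `seed + iteration`. Two procedures are supported:
#'
#' * **External prediction** ([predict.acp()]): every iteration re-splits
#'   the *full* training set 70/30 into proper-training and calibration
#'   parts, fits an ICP and scores the new compounds; medians are taken
#'   over all iterations.
#' * **Internal validation** ([internal_validation()]): every iteration
#'   first leaves out a random fraction (default 20%) of the training
#'   compounds, fits an ICP on the remainder, and scores only the left-out
#'   compounds. A compound's aggregated p-values are the medians over
#'   exactly the iterations in which it was left out, so they are genuinely
#'   out-of-sample.
#'
#' An iteration whose calibration part misses a class is resampled with a
#' shifted seed (bounded retries), which matters for the extremely
#' imbalanced libraries typical of primary screens.
#'
#' @param x numeric feature matrix or a [screening_library()].
#' @param y activity labels; ignored when `x` is a `screening_library`.
#' @param n_iterations number of ICP repetitions (default 100).
#' @param leave_out_fraction fraction left out per internal-validation
#'   iteration (default 0.2).
#' @param proper_fraction,n_trees,mondrian passed to [fit_icp()].
#' @param seed integer master seed.
#' @return An object of class `acp`.
#' @export
#' @examples
#' lib <- simulate_library(library_spec(n_compounds = 400, hit_rate = 0.2,
#'                                      effect_size = 2, seed = 3))
#' model <- acp(lib, n_iterations = 5, n_trees = 50, seed = 1)
#' pv <- predict(model, lib$features[1:3, ])
acp <- function(x, y = NULL, n_iterations = 100, leave_out_fraction = 0.2,
                proper_fraction = 0.7, n_trees = 500, mondrian = TRUE,
                seed = 1) {
  if (inherits(x, "screening_library")) {
    y <- x$labels
    x <- x$features
  }
  x <- as.matrix(x)
  y <- as_activity_factor(y)
  if (nrow(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  stopifnot_scalar_number(n_iterations, "n_iterations", lower = 1)
  stopifnot_scalar_number(leave_out_fraction, "leave_out_fraction", 0, 1,
                          strict = TRUE)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  structure(
    list(
      x = x, y = y,
      n_iterations = as.integer(n_iterations),
      leave_out_fraction = leave_out_fraction,
      proper_fraction = proper_fraction,
      n_trees = n_trees, mondrian = mondrian,
      seed = as.integer(seed)
    ),
    class = "acp"
  )
}

#' @export
print.acp <- function(x, ...) {
  cat(sprintf(
    "Aggregated conformal predictor: %d iterations of a %d-tree ICP\n",
    x$n_iterations, x$n_trees
  ))
  cat(sprintf("  training data: %d compounds (%d active), %d features\n",
              nrow(x$x), sum(x$y == "active"), ncol(x$x)))
  invisible(x)
}

## Fit one ICP iteration, resampling with shifted seeds when a class is
## missing from the calibration (or proper-training) part.
fit_icp_retry <- function(x, y, proper_fraction, n_trees, mondrian,
                          iter_seed, max_retries = 25L) {
  for (r in 0:max_retries) {
    model <- tryCatch(
      fit_icp(x, y, proper_fraction = proper_fraction, n_trees = n_trees,
              mondrian = mondrian, seed = iter_seed + r * .retry_step),
      error = function(e) e
    )
    if (!inherits(model, "error")) {
      if (r > 0L) {
        message(sprintf(
          "iteration with seed %d resampled %d time(s) (unusable calibration split)",
          iter_seed, r
        ))
      }
      attr(model, "retries") <- r
      return(model)
    }
  }
  stop(sprintf(
    "calibration failed in all %d resampling attempts: %s",
    max_retries + 1L, conditionMessage(model)
  ), call. = FALSE)
}

#' Predict new compounds with an aggregated conformal predictor
#'
#' Runs the configured number of ICP iterations, each on a fresh random
#' proper/calibration split of the full training data, and returns the
#' per-compound, per-class median p-values. With `n_iterations = 1` the
#' result is identical to a single [fit_icp()] with the derived seed
#' `seed + 1`.
#'
#' @param object an [acp()] model.
#' @param newdata numeric feature matrix or [screening_library()].
#' @param type,significance as in [predict.icp()].
#' @param ... unused.
#' @return As [predict.icp()].
#' @export
predict.acp <- function(object, newdata,
                        type = c("p.value", "set", "score"),
                        significance = 0.2, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "screening_library")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  B <- object$n_iterations
  m <- nrow(newdata)
  pa <- matrix(NA_real_, m, B)
  pi_ <- matrix(NA_real_, m, B)
  for (b in seq_len(B)) {
    model <- fit_icp_retry(
      object$x, object$y, object$proper_fraction, object$n_trees,
      object$mondrian, iter_seed = object$seed + b
    )
    pv <- predict(model, newdata, type = "p.value")
    pa[, b] <- pv$p_active
    pi_[, b] <- pv$p_inactive
  }
  if (type == "score") {
    stop("type = 'score' is not defined for an aggregated predictor",
         call. = FALSE)
  }
  p_active <- apply(pa, 1L, stats::median)
  p_inactive <- apply(pi_, 1L, stats::median)
  if (type == "set") {
    return(assign_label_set(p_active, p_inactive, significance))
  }
  data.frame(p_active = p_active, p_inactive = p_inactive)
}

#' Internal leave-out validation of an aggregated conformal predictor
#'
#' @param object a fitted model supporting internal validation.
#' @param ... method-specific arguments.
#' @return See methods.
#' @export
internal_validation <- function(object, ...) UseMethod("internal_validation")

#' @describeIn internal_validation Each iteration leaves out
#'   `leave_out_fraction` of the training compounds, fits an ICP on the
#'   remainder and scores the left-out compounds; per-compound p-values are
#'   medians over the iterations in which the compound was left out. A
#'   compound never left out gets `NA` p-values (and is excluded from any
#'   downstream metric) rather than an in-sample estimate; its identity is
#'   reported via the `n_iterations` column.
#' @return For `acp`: a data frame with one row per training compound and
#'   columns `p_active`, `p_inactive`, `n_iterations` (how many iterations
#'   contributed), `truth`.
#' @export
internal_validation.acp <- function(object, ...) {
  n <- nrow(object$x)
  B <- object$n_iterations
  pa <- matrix(NA_real_, n, B)
  pi_ <- matrix(NA_real_, n, B)
  n_out <- max(1L, round(object$leave_out_fraction * n))
  max_retries <- 25L
  for (b in seq_len(B)) {
    ## an iteration whose leave-out draw leaves too few compounds of a class
    ## to split is resampled wholesale (fresh leave-out draw, shifted seed)
    model <- NULL
    for (r in 0:max_retries) {
      out_idx <- with_seed(object$seed + b + r * .retry_step,
                           sort(sample.int(n, n_out)))
      in_idx <- setdiff(seq_len(n), out_idx)
      if (any(table(object$y[in_idx]) < 2L)) next
      model <- tryCatch(
        fit_icp_retry(
          object$x[in_idx, , drop = FALSE], object$y[in_idx],
          object$proper_fraction, object$n_trees, object$mondrian,
          iter_seed = object$seed + b + r * .retry_step + .seed_offset,
          max_retries = 5L
        ),
        error = function(e) NULL
      )
      if (!is.null(model)) {
        if (r > 0L) {
          message(sprintf(
            "internal validation iteration %d: leave-out draw resampled %d time(s)",
            b, r
          ))
        }
        break
      }
    }
    if (is.null(model)) {
      stop("internal validation: no usable leave-out split found",
           call. = FALSE)
    }
    pv <- predict(model, object$x[out_idx, , drop = FALSE], type = "p.value")
    pa[out_idx, b] <- pv$p_active
    pi_[out_idx, b] <- pv$p_inactive
  }
  counts <- rowSums(!is.na(pa))
  med <- function(m) {
    apply(m, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else stats::median(v)
    })
  }
  data.frame(
    p_active = med(pa), p_inactive = med(pi_),
    n_iterations = counts, truth = object$y
  )
}
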