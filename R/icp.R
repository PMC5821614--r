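#' Fit an inductive conformal classifier on random-forest vote fractions
#'
#' Splits the supplied training compounds into a proper-training part and a
#' calibration part, grows a random-forest ensemble on the proper-training
#' part only, and records the calibration compounds' conformity scores. The
#' conformity score of a compound for a class is the fraction of trees in
#' the ensemble voting for that class, so scores lie in \[0, 1\] and the two
#' class scores of a compound sum to one.
#'
#' Calibration is label-conditional (Mondrian) by default: a calibration
#' compound's score for its *true* class enters only that class's sorted
#' list. This yields per-class validity, which is what makes conformal
#' predictors attractive for heavily imbalanced activity data — the minority
#' (active) class gets its own error-rate guarantee instead of being
#' swamped by the inactives. Setting `mondrian = FALSE` pools the true-class
#' scores of all calibration compounds into one unconditional list.
#'
#' The proper-training part receives `floor(proper_fraction * n)` compounds
#' and the remainder goes to calibration, so the calibration part is
#' non-empty whenever `n >= 2`.
#'
#' @param x numeric feature matrix (one row per compound) or a
#'   [screening_library()].
#' @param y activity labels (`"active"`/`"inactive"`); ignored when `x` is a
#'   `screening_library`.
#' @param proper_fraction fraction of compounds used to grow the ensemble
#'   (default 0.7; the remaining 30% calibrate).
#' @param n_trees ensemble size (default 500 trees).
#' @param mondrian logical; label-conditional calibration (default `TRUE`).
#' @param seed integer seed controlling the split and the forest.
#' @return An object of class `icp` with components `forest`,
#'   `calib_active` and `calib_inactive` (ascending sorted calibration
#'   score lists), `proper_idx`, `calib_idx`, `mondrian`, `seed`.
#' @seealso [predict.icp()], [p_value()], [assign_label_set()]
#' @export
#' @examples
#' lib <- simulate_library(library_spec(n_compounds = 300, hit_rate = 0.2,
#'                                      effect_size = 2, seed = 7))
#' model <- fit_icp(lib, n_trees = 50, seed = 1)
#' head(predict(model, lib$features[1:5, ]))
fit_icp <- function(x, y = NULL, proper_fraction = 0.7, n_trees = 500,
                    mondrian = TRUE, seed = 1) {
  if (inherits(x, "screening_library")) {
    y <- x$labels
    x <- x$features
  }
  x <- as.matrix(x)
  y <- as_activity_factor(y)
  n <- nrow(x)
  if (length(y) != n) stop("'x' and 'y' lengths differ", call. = FALSE)
  stopifnot_scalar_number(proper_fraction, "proper_fraction", 0, 1,
                          strict = TRUE)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  with_seed(seed, {
    perm <- sample.int(n)
    n_prop <- floor(proper_fraction * n)
    proper_idx <- sort(perm[seq_len(n_prop)])
    calib_idx <- sort(perm[-seq_len(n_prop)])
    y_prop <- y[proper_idx]
    y_cal <- y[calib_idx]
    if (any(table(y_prop) == 0L)) {
      stop("a class is absent from the proper-training part; cannot fit",
           call. = FALSE)
    }
    if (any(table(y_cal) == 0L)) {
      stop("a class is absent from the calibration part; cannot calibrate",
           call. = FALSE)
    }
    forest <- randomForest::randomForest(
      x[proper_idx, , drop = FALSE], y_prop, ntree = n_trees
    )
    scores <- vote_fractions(forest, x[calib_idx, , drop = FALSE])
    if (mondrian) {
      calib_active <- sort(scores[y_cal == "active", "active"])
      calib_inactive <- sort(scores[y_cal == "inactive", "inactive"])
    } else {
      pooled <- sort(ifelse(y_cal == "active",
                            scores[, "active"], scores[, "inactive"]))
      calib_active <- pooled
      calib_inactive <- pooled
    }
    structure(
      list(
        forest = forest,
        calib_active = calib_active, calib_inactive = calib_inactive,
        proper_idx = proper_idx, calib_idx = calib_idx,
        mondrian = mondrian, n_trees = n_trees,
        n_features = ncol(x), seed = as.integer(seed)
      ),
      class = "icp"
    )
  })
}

#' @export
print.icp <- function(x, ...) {
  cat(sprintf(
    "Inductive conformal classifier (%d trees, %s calibration)\n",
    x$n_trees, if (x$mondrian) "Mondrian" else "unconditional"
  ))
  cat(sprintf(
    "  proper training: %d compounds; calibration: %d active / %d inactive\n",
    length(x$proper_idx), length(x$calib_active), length(x$calib_inactive)
  ))
  invisible(x)
}

## Per-class vote fractions of the ensemble for each row of `features`.
vote_fractions <- function(forest, features) {
  p <- stats::predict(forest, features, type = "prob")
  p[, .classes, drop = FALSE]
}

#' Conformal p-values from a sorted calibration list
#'
#' The conformal p-value of a new conformity score against a calibration
#' list of size n is the fraction of the augmented (n + 1)-element list that
#' lies strictly below the new score: `sum(calibration < score) / (n + 1)`.
#' Placing a score above all nine members of a calibration list, for
#' example, puts it at position 10 of the augmented list and yields
#' 9/10 = 0.9; a score at position 9 (eight members strictly below) yields
#' 0.8. Tied calibration scores do not count as "below".
#'
#' @param score numeric vector of conformity scores in \[0, 1\].
#' @param calibration numeric vector of calibration scores (any order).
#' @param smoothed logical; if `TRUE`, each tie contributes with
#'   probability 1/2 (its expected randomised-smoothing contribution),
#'   giving exact rather than conservative validity. Default `FALSE`.
#' @return Numeric vector of p-values in \[0, 1\], one per score.
#' @export
#' @examples
#' p_value(0.75, c(0.1, 0.2, 0.3, 0.35, 0.4, 0.5, 0.6, 0.7, 0.9))  # 0.8
p_value <- function(score, calibration, smoothed = FALSE) {
  if (length(calibration) == 0L) {
    stop("calibration list is empty", call. = FALSE)
  }
  if (!is.numeric(score) || !is.numeric(calibration)) {
    stop("'score' and 'calibration' must be numeric", call. = FALSE)
  }
  cal <- sort(calibration)
  n1 <- length(cal) + 1L
  below <- findInterval(score, cal, left.open = TRUE)
  if (smoothed) {
    leq <- findInterval(score, cal)
    below <- below + 0.5 * (leq - below)
  }
  below / n1
}

#' Assign a conformal label set
#'
#' A class is included in a compound's prediction set when its conformal
#' p-value is greater than or equal to the significance level. Both classes
#' can qualify (the "both" set), exactly one, or neither (the "empty" set).
#'
#' @param p_active,p_inactive numeric vectors of per-class p-values in
#'   \[0, 1\].
#' @param significance the significance level, in (0, 1); the confidence
#'   level is its complement.
#' @return Character vector with values `"active"`, `"inactive"`, `"both"`
#'   or `"empty"`.
#' @export
#' @examples
#' assign_label_set(0.80, 0.0, significance = 0.20)  # "active"
#' assign_label_set(0.5, 0.5, significance = 0.20)   # "both"
assign_label_set <- function(p_active, p_inactive, significance) {
  stopifnot_scalar_number(significance, "significance", 0, 1, strict = TRUE)
  if (length(p_active) != length(p_inactive)) {
    stop("'p_active' and 'p_inactive' lengths differ", call. = FALSE)
  }
  bad <- !is.na(p_active) & (p_active < 0 | p_active > 1) |
    !is.na(p_inactive) & (p_inactive < 0 | p_inactive > 1)
  if (any(bad)) stop("p-values must lie in [0, 1]", call. = FALSE)
  in_a <- p_active >= significance
  in_i <- p_inactive >= significance
  out <- rep(NA_character_, length(p_active))
  ok <- !is.na(in_a) & !is.na(in_i)
  out[ok & in_a & in_i] <- "both"
  out[ok & in_a & !in_i] <- "active"
  out[ok & !in_a & in_i] <- "inactive"
  out[ok & !in_a & !in_i] <- "empty"
  out
}

#' Predict with an inductive conformal classifier
#'
#' @param object an [fit_icp()] model.
#' @param newdata numeric feature matrix or [screening_library()].
#' @param type `"p.value"` (default) for per-class conformal p-values,
#'   `"set"` for label sets at `significance`, `"score"` for raw vote
#'   fractions.
#' @param significance significance level used when `type = "set"`.
#' @param ... unused.
#' @return For `"p.value"`, a data frame with columns `p_active`,
#'   `p_inactive`; for `"score"`, a matrix of vote fractions; for `"set"`,
#'   a character vector of label sets.
#' @export
predict.icp <- function(object, newdata, type = c("p.value", "set", "score"),
                        significance = 0.2, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "screening_library")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("newdata has %d features; model was trained on %d",
                 ncol(newdata), object$n_features), call. = FALSE)
  }
  scores <- vote_fractions(object$forest, newdata)
  if (type == "score") return(scores)
  pa <- p_value(scores[, "active"], object$calib_active)
  pi_ <- p_value(scores[, "inactive"], object$calib_inactive)
  if (type == "set") return(assign_label_set(pa, pi_, significance))
  data.frame(p_active = pa, p_inactive = pi_)
}
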