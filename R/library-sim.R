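#' Specify a synthetic screening library
#'
#' A `library_spec` captures the statistical shape of a high-throughput
#' screening library: its size, the fraction of active compounds (hit rate),
#' and a feature space that is either fingerprint-like (sparse binary bits)
#' or descriptor-like (continuous, standard normal). Activity is linked to a
#' subset of "informative" features through a logistic model, so the
#' separability of the two classes can be controlled with a single
#' effect-size knob while the marginal hit rate is held exactly at the
#' requested value.
#'
#' Public bioassay screens typically combine very low hit rates (well under
#' 1% up to roughly 12%) with libraries of tens to hundreds of thousands of
#' compounds; the defaults here describe a scaled-down library in that
#' regime that is convenient for simulation studies.
#'
#' @param n_compounds number of compounds in the library.
#' @param hit_rate marginal probability that a compound is active, in (0,1).
#' @param n_features width of the feature matrix.
#' @param feature_kind `"continuous"` for descriptor-like standard-normal
#'   features, `"binary"` for sparse fingerprint-like bits.
#' @param n_informative number of features that carry signal about activity
#'   (the first `n_informative` columns); must not exceed `n_features`.
#' @param effect_size log-odds weight given to each informative feature.
#'   `0` makes labels independent of the features.
#' @param label_noise probability in \[0, 0.5) that a drawn label is
#'   flipped, mimicking assay noise.
#' @param density for binary features, the Bernoulli bit density
#'   (default 0.02, mimicking sparse hashed fingerprints).
#' @param seed integer seed; the same spec and seed reproduce the library
#'   bit-exactly.
#' @return An object of class `library_spec`.
#' @seealso [simulate_library()]
#' @export
#' @examples
#' library_spec(n_compounds = 1000, hit_rate = 0.05, seed = 1)
library_spec <- function(n_compounds = 5000, hit_rate = 0.05,
                         n_features = 32, feature_kind = c("continuous", "binary"),
                         n_informative = 16, effect_size = 1,
                         label_noise = 0, density = 0.02, seed = 1) {
  feature_kind <- match.arg(feature_kind)
  stopifnot_scalar_number(n_compounds, "n_compounds", lower = 1)
  stopifnot_scalar_number(hit_rate, "hit_rate", 0, 1, strict = TRUE)
  stopifnot_scalar_number(n_features, "n_features", lower = 1)
  stopifnot_scalar_number(n_informative, "n_informative", 0, n_features)
  stopifnot_scalar_number(effect_size, "effect_size", lower = 0)
  stopifnot_scalar_number(label_noise, "label_noise", 0, 0.5)
  if (label_noise >= 0.5) stop("'label_noise' must be < 0.5", call. = FALSE)
  stopifnot_scalar_number(density, "density", 0, 1, strict = TRUE)
  stopifnot_scalar_number(seed, "seed")
  structure(
    list(
      n_compounds = as.integer(n_compounds), hit_rate = hit_rate,
      n_features = as.integer(n_features), feature_kind = feature_kind,
      n_informative = as.integer(n_informative), effect_size = effect_size,
      label_noise = label_noise, density = density, seed = as.integer(seed)
    ),
    class = "library_spec"
  )
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic library spec: %d compounds, hit rate %.4g, %d %s features (%d informative, effect size %.3g)\n",
    x$n_compounds, x$hit_rate, x$n_features, x$feature_kind,
    x$n_informative, x$effect_size
  ))
  if (x$label_noise > 0) cat(sprintf("  label noise: %.3g\n", x$label_noise))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Construct a screening library container
#'
#' Bundles compound identifiers, a numeric feature matrix and binary
#' activity labels into the container consumed by the modelling and
#' screening functions. Identifiers must be unique and all three components
#' must agree in length.
#'
#' @param compound_ids character vector of unique compound identifiers.
#' @param features numeric matrix, one row per compound.
#' @param labels character or factor vector with values `"active"` /
#'   `"inactive"`.
#' @param provenance optional record of where the library came from (a
#'   [library_spec()] or a file path).
#' @return An object of class `screening_library`.
#' @export
screening_library <- function(compound_ids, features, labels,
                              provenance = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  compound_ids <- as.character(compound_ids)
  labels <- as_activity_factor(labels)
  if (nrow(features) != length(compound_ids) ||
      nrow(features) != length(labels)) {
    stop("compound_ids, features rows and labels must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(compound_ids)) {
    stop("compound_ids must be unique", call. = FALSE)
  }
  rownames(features) <- compound_ids
  structure(
    list(compound_ids = compound_ids, features = features, labels = labels,
         provenance = provenance),
    class = "screening_library"
  )
}

#' @export
print.screening_library <- function(x, ...) {
  n <- length(x$compound_ids)
  n_act <- sum(x$labels == "active")
  cat(sprintf(
    "Screening library: %d compounds x %d features; %d active (%.3g%%)\n",
    n, ncol(x$features), n_act, 100 * n_act / n
  ))
  invisible(x)
}

#' Simulate a synthetic screening library
#'
#' Draws a library according to a [library_spec()]. Features are sampled
#' i.i.d. per compound (sparse Bernoulli bits or standard normals); a linear
#' score over the informative features feeds a logistic model whose
#' intercept is solved numerically so that the *marginal* active probability
#' equals the requested hit rate; labels are then drawn independently per
#' compound and optionally flipped with the label-noise probability. Rows
#' are therefore exchangeable by construction, which is the assumption
#' underlying conformal validity.
#'
#' @param spec a [library_spec()].
#' @return A [screening_library()] whose `provenance` is `spec`.
#' @export
#' @examples
#' lib <- simulate_library(library_spec(n_compounds = 500, hit_rate = 0.1,
#'                                      seed = 42))
#' table(lib$labels)
simulate_library <- function(spec) {
  if (!inherits(spec, "library_spec")) {
    stop("'spec' must be a library_spec object", call. = FALSE)
  }
  with_seed(spec$seed, {
    n <- spec$n_compounds
    k <- spec$n_features
    x <- if (spec$feature_kind == "binary") {
      matrix(as.double(stats::rbinom(n * k, 1L, spec$density)), n, k)
    } else {
      matrix(stats::rnorm(n * k), n, k)
    }
    colnames(x) <- sprintf("f_%d", seq_len(k) - 1L)
    score <- if (spec$n_informative > 0L && spec$effect_size > 0) {
      as.numeric(x[, seq_len(spec$n_informative), drop = FALSE] %*%
                   rep(spec$effect_size, spec$n_informative))
    } else {
      numeric(n)
    }
    alpha <- solve_intercept(score, spec$hit_rate)
    p_active <- stats::plogis(alpha + score)
    active <- stats::rbinom(n, 1L, p_active) == 1L
    if (spec$label_noise > 0) {
      flip <- stats::rbinom(n, 1L, spec$label_noise) == 1L
      active <- xor(active, flip)
    }
    screening_library(
      compound_ids = sprintf("cmpd%07d", seq_len(n)),
      features = x,
      labels = ifelse(active, "active", "inactive"),
      provenance = spec
    )
  })
}

## Solve for the logistic intercept giving mean(plogis(alpha + score)) = target.
solve_intercept <- function(score, target) {
  if (all(score == 0)) return(stats::qlogis(target))
  f <- function(a) mean(stats::plogis(a + score)) - target
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-12)$root
}

#' Write / read a screening library as CSV
#'
#' `write_library()` stores a library as a plain CSV with columns
#' `compound_id`, `label`, `f_0` ... `f_{k-1}`, plus a JSON sidecar
#' (`<path>.json`) recording the generating spec when the library is
#' synthetic. `read_library()` reads the same layout back.
#'
#' @param library a [screening_library()].
#' @param path CSV file path.
#' @return `write_library()` returns `path` invisibly; `read_library()`
#'   returns a [screening_library()].
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "screening_library"))
  df <- data.frame(
    compound_id = library$compound_ids,
    label = as.character(library$labels),
    library$features,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (inherits(library$provenance, "library_spec")) {
    jsonlite::write_json(unclass(library$provenance),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("compound_id", "label")
  if (!all(need %in% names(df))) {
    stop("library CSV must have 'compound_id' and 'label' columns",
         call. = FALSE)
  }
  feat_cols <- setdiff(names(df), need)
  screening_library(
    compound_ids = df$compound_id,
    features = as.matrix(df[, feat_cols, drop = FALSE]),
    labels = df$label,
    provenance = path
  )
}

#' Split a library into subsets by index
#'
#' @param library a [screening_library()].
#' @param idx integer index vector of the rows to keep.
#' @return A [screening_library()] restricted to `idx`.
#' @keywords internal
#' @export
subset_library <- function(library, idx) {
  screening_library(
    compound_ids = library$compound_ids[idx],
    features = library$features[idx, , drop = FALSE],
    labels = library$labels[idx],
    provenance = library$provenance
  )
}
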