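#' Conformal validity
#'
#' Validity is the fraction of prediction sets containing the true label: a
#' single-label prediction is correct when it matches the truth, a "both"
#' prediction is always correct, an "empty" prediction is always incorrect.
#' For exchangeable data a (Mondrian) conformal predictor at significance
#' level eps has per-class validity of at least 1 - eps in expectation.
#'
#' @param label_sets character vector of label sets as produced by
#'   [assign_label_set()] (`"active"`, `"inactive"`, `"both"`, `"empty"`);
#'   `NA` entries are dropped together with their truths.
#' @param truth true labels (`"active"`/`"inactive"`).
#' @param restrict_to_class optional class; when given, validity is
#'   computed only over compounds whose *true* label is that class.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' cp_validity(c("active", "both", "empty"),
#'             c("active", "inactive", "active"))  # 2/3
cp_validity <- function(label_sets, truth, restrict_to_class = NULL) {
  truth <- as_activity_factor(truth)
  if (length(label_sets) != length(truth)) {
    stop("'label_sets' and 'truth' lengths differ", call. = FALSE)
  }
  keep <- !is.na(label_sets)
  if (!is.null(restrict_to_class)) {
    restrict_to_class <- match.arg(restrict_to_class, .classes)
    keep <- keep & truth == restrict_to_class
  }
  label_sets <- label_sets[keep]
  truth <- as.character(truth)[keep]
  if (length(label_sets) == 0L) return(NA_real_)
  mean(label_sets == "both" | label_sets == truth)
}

#' Conformal efficiency
#'
#' Efficiency is the fraction of prediction sets that contain exactly one
#' label; a more efficient predictor commits to a single class more often.
#' "Both" and "empty" sets both count against efficiency.
#'
#' @param label_sets as in [cp_validity()].
#' @param truth true labels; required only when `restrict_to_class` is
#'   given (the restriction conditions on the *true* label).
#' @param restrict_to_class optional class to condition on.
#' @return A fraction in \[0, 1\].
#' @export
cp_efficiency <- function(label_sets, truth = NULL,
                          restrict_to_class = NULL) {
  keep <- !is.na(label_sets)
  if (!is.null(restrict_to_class)) {
    if (is.null(truth)) {
      stop("'truth' is required when restricting to a class", call. = FALSE)
    }
    truth <- as_activity_factor(truth)
    if (length(truth) != length(label_sets)) {
      stop("'label_sets' and 'truth' lengths differ", call. = FALSE)
    }
    restrict_to_class <- match.arg(restrict_to_class, .classes)
    keep <- keep & truth == restrict_to_class
  }
  if (length(keep) == 0L) {
    stop("no label sets to evaluate", call. = FALSE)
  }
  label_sets <- label_sets[keep]
  if (length(label_sets) == 0L) return(NA_real_)
  mean(label_sets %in% .classes)
}

#' Summarise conformal performance at one significance level
#'
#' Computes overall and per-class validity and efficiency, plus the counts
#' of the four possible prediction-set outcomes, from a p-value table.
#' Compounds with missing p-values (e.g. never left out during internal
#' validation) are excluded and counted in `n_excluded`.
#'
#' @param pvals data frame with columns `p_active` and `p_inactive`.
#' @param truth true labels.
#' @param significance significance level in (0, 1).
#' @return A one-row data frame with columns `significance`,
#'   `validity_overall`, `validity_active`, `validity_inactive`,
#'   `efficiency_overall`, `efficiency_active`, `efficiency_inactive`,
#'   `n_single_active`, `n_single_inactive`, `n_both`, `n_empty`,
#'   `n_excluded`.
#' @export
conformal_metrics <- function(pvals, truth, significance) {
  truth <- as_activity_factor(truth)
  sets <- assign_label_set(pvals$p_active, pvals$p_inactive, significance)
  ok <- !is.na(sets)
  data.frame(
    significance = significance,
    validity_overall = cp_validity(sets, truth),
    validity_active = cp_validity(sets, truth, "active"),
    validity_inactive = cp_validity(sets, truth, "inactive"),
    efficiency_overall = cp_efficiency(sets),
    efficiency_active = cp_efficiency(sets, truth, "active"),
    efficiency_inactive = cp_efficiency(sets, truth, "inactive"),
    n_single_active = sum(sets[ok] == "active"),
    n_single_inactive = sum(sets[ok] == "inactive"),
    n_both = sum(sets[ok] == "both"),
    n_empty = sum(sets[ok] == "empty"),
    n_excluded = sum(!ok)
  )
}
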