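#' Gain-cost parameters
#'
#' The screening economy is summarised by two numbers: the gain credited
#' per confirmed hit and the cost of screening one compound (in the same
#' arbitrary units). A hit gain of 400 against per-compound costs of 6
#' (cheap biochemical assay), 10 (medium) or 14 (complex phenotypic assay)
#' spans a range where a full unselected HTS campaign is roughly breakeven.
#'
#' @param hit_gain gain per identified hit (default 400).
#' @param screen_cost cost per screened compound (default 10).
#' @return An object of class `gain_cost_params`.
#' @export
gain_cost_params <- function(hit_gain = 400, screen_cost = 10) {
  stopifnot_scalar_number(hit_gain, "hit_gain", lower = 0, strict = TRUE)
  stopifnot_scalar_number(screen_cost, "screen_cost", lower = 0,
                          strict = TRUE)
  structure(list(hit_gain = hit_gain, screen_cost = screen_cost),
            class = "gain_cost_params")
}

#' Total gain of a two-round screen
#'
#' The gain-cost function is linear: every screened compound costs
#' `screen_cost` and every identified hit earns `hit_gain`, summed over the
#' initial (training) screen and the follow-up (test) screen:
#' \deqn{gain = g \cdot h_{train} - c \cdot s_{train} + g \cdot h_{test} -
#'   c \cdot s_{test}}
#' with \eqn{g} the hit gain, \eqn{c} the screening cost, \eqn{h} the hits
#' found and \eqn{s} the compounds screened in each round.
#'
#' @param n_hits_train,n_screened_train hits found in / size of the initial
#'   screen.
#' @param n_hits_test,n_screened_test hits found in / size of the follow-up
#'   screen.
#' @param params a [gain_cost_params()].
#' @return The total gain (may be negative).
#' @export
#' @examples
#' total_gain(0, 0, 5, 100, gain_cost_params(400, 10))  # 1000
total_gain <- function(n_hits_train, n_screened_train, n_hits_test,
                       n_screened_test, params = gain_cost_params()) {
  counts <- c(n_hits_train, n_screened_train, n_hits_test, n_screened_test)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  if (n_hits_train > n_screened_train || n_hits_test > n_screened_test) {
    stop("hits cannot exceed the number of screened compounds",
         call. = FALSE)
  }
  params$hit_gain * n_hits_train - params$screen_cost * n_screened_train +
    params$hit_gain * n_hits_test - params$screen_cost * n_screened_test
}

#' Evaluate screening policies over a significance-level grid
#'
#' For each significance level, the compounds whose internal-validation
#' prediction set is exactly `{active}` form the candidate selection. The
#' selection fraction and the hit fraction among internal-validation
#' compounds are scaled proportionally to the `n_remaining` unscreened
#' compounds to give the estimated gain of screening that predicted-active
#' subset. Two baseline policies are appended: `screen_all` (screen every
#' remaining compound, hits projected from the training-screen hit rate)
#' and `screen_none` (gain 0 by definition).
#'
#' The default grid corresponds to confidence levels 90/80/70/60%.
#' Compounds with missing internal p-values are excluded from the rate
#' estimates (their count is in `n_excluded`).
#'
#' @param pvals internal-validation p-value table (columns `p_active`,
#'   `p_inactive`), e.g. from [internal_validation()].
#' @param truth true labels of the same compounds.
#' @param grid significance levels to scan (default `c(0.1, 0.2, 0.3,
#'   0.4)`).
#' @param params a [gain_cost_params()].
#' @param n_remaining number of unscreened compounds the estimates are
#'   scaled to.
#' @param n_train,n_train_hits size of and hits in the already-screened
#'   training round (enter the reported total gain as sunk terms).
#' @return A data frame, one row per policy (`level_<eps>`, `screen_all`,
#'   `screen_none`), with estimated test and total gains plus
#'   validity/efficiency snapshots; inputs are carried as attributes for
#'   [decide_screening()].
#' @export
evaluate_significance_grid <- function(pvals, truth,
                                       grid = c(0.1, 0.2, 0.3, 0.4),
                                       params = gain_cost_params(),
                                       n_remaining, n_train, n_train_hits) {
  if (length(grid) == 0L) stop("'grid' must be nonempty", call. = FALSE)
  for (g in grid) stopifnot_scalar_number(g, "grid level", 0, 1,
                                          strict = TRUE)
  truth <- as_activity_factor(truth)
  ok <- !is.na(pvals$p_active) & !is.na(pvals$p_inactive)
  n_eval <- sum(ok)
  if (n_eval == 0L) stop("no evaluable internal p-values", call. = FALSE)

  rows <- lapply(sort(grid), function(eps) {
    sets <- assign_label_set(pvals$p_active[ok], pvals$p_inactive[ok], eps)
    sel <- sets == "active"
    n_selected <- sum(sel)
    n_hits_selected <- sum(sel & truth[ok] == "active")
    est_screened <- n_selected / n_eval * n_remaining
    est_hits <- n_hits_selected / n_eval * n_remaining
    test_gain <- params$hit_gain * est_hits - params$screen_cost * est_screened
    met <- conformal_metrics(pvals[ok, , drop = FALSE], truth[ok], eps)
    data.frame(
      policy = sprintf("level_%g", eps), significance = eps,
      n_selected_internal = n_selected,
      n_hits_internal = n_hits_selected,
      est_screened_test = est_screened, est_hits_test = est_hits,
      estimated_test_gain = test_gain,
      estimated_total_gain = test_gain + params$hit_gain * n_train_hits -
        params$screen_cost * n_train,
      validity_active = met$validity_active,
      validity_inactive = met$validity_inactive,
      efficiency_active = met$efficiency_active,
      efficiency_inactive = met$efficiency_inactive,
      stringsAsFactors = FALSE
    )
  })

  train_rate <- n_train_hits / n_train
  all_gain <- params$hit_gain * train_rate * n_remaining -
    params$screen_cost * n_remaining
  baseline <- function(policy, est_screened, est_hits, test_gain) {
    data.frame(
      policy = policy, significance = NA_real_,
      n_selected_internal = NA_integer_, n_hits_internal = NA_integer_,
      est_screened_test = est_screened, est_hits_test = est_hits,
      estimated_test_gain = test_gain,
      estimated_total_gain = test_gain + params$hit_gain * n_train_hits -
        params$screen_cost * n_train,
      validity_active = NA_real_, validity_inactive = NA_real_,
      efficiency_active = NA_real_, efficiency_inactive = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    do.call(rbind, rows),
    baseline("screen_all", n_remaining, train_rate * n_remaining, all_gain),
    baseline("screen_none", 0, 0, 0)
  )
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "n_train") <- n_train
  attr(out, "n_train_hits") <- n_train_hits
  attr(out, "n_remaining") <- n_remaining
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Decide what to screen next
#'
#' Picks the policy with the largest estimated test-side gain among the
#' scanned significance levels, screening everything, and screening
#' nothing. If every alternative projects a non-positive gain the decision
#' is to stop. Ties are broken toward the higher-confidence (lower
#' significance) level, then toward screening fewer compounds. The
#' training-screen cost is sunk at decision time, so only test-side gains
#' are compared; totals including the sunk terms are still reported.
#'
#' A low-expected-gain warning is attached when the cost of the initial
#' screen exceeds five times the estimated subset gain: historically such
#' screens rarely recover an overall profit, so the projected gain should
#' be treated with caution.
#'
#' @param evaluations the data frame returned by
#'   [evaluate_significance_grid()].
#' @return An object of class `screening_decision` with elements `mode`
#'   (`"screen_subset"`, `"screen_all"` or `"stop"`), `significance`
#'   (for subsets), `estimated_test_gain`, `estimated_total_gain`,
#'   `warnings`, and the policy table.
#' @export
decide_screening <- function(evaluations) {
  need <- c("policy", "significance", "estimated_test_gain",
            "est_screened_test")
  if (!all(need %in% names(evaluations))) {
    stop("'evaluations' must come from evaluate_significance_grid()",
         call. = FALSE)
  }
  params <- attr(evaluations, "params")
  n_train <- attr(evaluations, "n_train")
  gains <- evaluations$estimated_test_gain
  warnings <- character()

  if (all(gains <= 0)) {
    mode <- "stop"
    chosen <- evaluations[evaluations$policy == "screen_none", ]
  } else {
    ## ties: larger gain, then lower significance (baselines last), then
    ## fewer screened compounds
    sig_rank <- ifelse(is.na(evaluations$significance), Inf,
                       evaluations$significance)
    ord <- order(-gains, sig_rank, evaluations$est_screened_test)
    chosen <- evaluations[ord[1L], ]
    mode <- switch(chosen$policy,
                   screen_all = "screen_all",
                   screen_none = "stop",
                   "screen_subset")
  }
  if (mode == "screen_subset" && !is.null(params) && !is.null(n_train)) {
    if (params$screen_cost * n_train > 5 * chosen$estimated_test_gain) {
      warnings <- c(warnings, paste(
        "low expected gain: the cost of the initial screen exceeds five",
        "times the estimated gain of screening the predicted subset"
      ))
    }
  }
  structure(
    list(
      mode = mode,
      significance = if (mode == "screen_subset") chosen$significance else NULL,
      estimated_test_gain = chosen$estimated_test_gain,
      estimated_total_gain = chosen$estimated_total_gain,
      est_screened_test = chosen$est_screened_test,
      est_hits_test = chosen$est_hits_test,
      warnings = warnings,
      params = params,
      evaluations = evaluations,
      selected_ids = character(),
      realized_test_gain = NULL
    ),
    class = "screening_decision"
  )
}

#' @export
print.screening_decision <- function(x, ...) {
  lab <- switch(x$mode,
                screen_subset = sprintf(
                  "screen predicted actives at significance %.2g (confidence %.0f%%)",
                  x$significance, 100 * (1 - x$significance)),
                screen_all = "screen all remaining compounds",
                stop = "stop: no further screening")
  cat("Screening decision:", lab, "\n")
  cat(sprintf("  estimated test gain: %.1f (total incl. initial screen: %.1f)\n",
              x$estimated_test_gain, x$estimated_total_gain))
  if (length(x$selected_ids)) {
    cat(sprintf("  selected compounds: %d\n", length(x$selected_ids)))
  }
  if (!is.null(x$realized_test_gain)) {
    cat(sprintf("  realized test gain: %.1f\n", x$realized_test_gain))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
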