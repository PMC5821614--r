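#' Run the full iterative-screening workflow
#'
#' Implements the two-round screening strategy end to end:
#'
#' 1. a random initial screen of `initial_fraction` (default 20%) of the
#'    library — random rather than stratified, since a simple random draw
#'    is what keeps the screened and unscreened compounds exchangeable and
#'    hence the conformal guarantee intact;
#' 2. an aggregated conformal predictor trained on the screened compounds,
#'    with leave-out [internal_validation()];
#' 3. a significance-level scan of the gain-cost function
#'    ([evaluate_significance_grid()]) and a [decide_screening()] call per
#'    screening cost: screen the predicted actives, screen everything left,
#'    or stop;
#' 4. prediction of the remaining compounds and selection of those whose
#'    aggregated prediction set is exactly `{active}` at the chosen level;
#' 5. evaluation of the realized gain against the best gain any scanned
#'    policy could have achieved on the remaining compounds
#'    ([oracle_best_gain()]), with a percent-regret report.
#'
#' Step 5 uses the true labels of the remaining compounds and is meant for
#' benchmarking on fully labelled (synthetic or retrospective) libraries;
#' in a prospective campaign the decision and selection list from steps
#' 3-4 are the actionable output.
#'
#' @param library a fully labelled [screening_library()].
#' @param initial_fraction fraction screened in round one (default 0.2).
#' @param n_iterations ACP iterations (default 100).
#' @param grid significance levels to scan (default `c(0.1, 0.2, 0.3,
#'   0.4)`, i.e. confidence 90/80/70/60%).
#' @param hit_gain gain per identified hit (default 400).
#' @param screen_cost one or more per-compound screening costs (default
#'   `c(6, 10, 14)`); the predictor is shared, the decision is made per
#'   cost.
#' @param n_trees,proper_fraction,leave_out_fraction,mondrian passed to
#'   [acp()].
#' @param stratified draw the initial screen stratified by class. Off by
#'   default: stratification breaks exchangeability and with it the
#'   validity guarantee; use only for tiny libraries where a random draw
#'   risks missing a class.
#' @param seed integer master seed; the whole run is reproducible from it.
#' @return An object of class `iterative_screen`: per-cost
#'   [decide_screening()] decisions augmented with selections, realized
#'   gains, oracle comparisons and regret, plus the internal and test
#'   p-value tables.
#' @export
#' @examples
#' \donttest{
#' lib <- simulate_library(library_spec(n_compounds = 1500, hit_rate = 0.1,
#'                                      effect_size = 1.5, seed = 11))
#' run <- iterative_screen(lib, n_iterations = 10, n_trees = 100, seed = 1)
#' run
#' }
iterative_screen <- function(library, initial_fraction = 0.2,
                             n_iterations = 100,
                             grid = c(0.1, 0.2, 0.3, 0.4),
                             hit_gain = 400, screen_cost = c(6, 10, 14),
                             n_trees = 500, proper_fraction = 0.7,
                             leave_out_fraction = 0.2, mondrian = TRUE,
                             stratified = FALSE, seed = 1) {
  stopifnot(inherits(library, "screening_library"))
  stopifnot_scalar_number(initial_fraction, "initial_fraction", 0, 1,
                          strict = TRUE)
  n <- length(library$compound_ids)
  n_init <- round(initial_fraction * n)
  train_idx <- with_seed(seed, {
    if (stratified) {
      idx <- unlist(lapply(split(seq_len(n), library$labels), function(i) {
        sample(i, max(1L, round(initial_fraction * length(i))))
      }), use.names = FALSE)
      sort(idx)
    } else {
      sort(sample.int(n, n_init))
    }
  })
  y_train <- library$labels[train_idx]
  if (any(table(y_train) < 2L)) {
    stop(paste(
      "the initial screen contains fewer than 2 compounds of a class;",
      "enlarge the library or the initial fraction (or, accepting the",
      "loss of the validity guarantee, use stratified = TRUE)"
    ), call. = FALSE)
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  train <- subset_library(library, train_idx)
  test <- subset_library(library, test_idx)
  n_train_hits <- sum(y_train == "active")

  model <- acp(train, n_iterations = n_iterations,
               leave_out_fraction = leave_out_fraction,
               proper_fraction = proper_fraction, n_trees = n_trees,
               mondrian = mondrian, seed = seed)
  internal <- internal_validation(model)
  test_pvals <- predict(model, test)

  decisions <- lapply(screen_cost, function(cost) {
    params <- gain_cost_params(hit_gain = hit_gain, screen_cost = cost)
    ev <- evaluate_significance_grid(
      internal, internal$truth, grid = grid, params = params,
      n_remaining = length(test_idx), n_train = length(train_idx),
      n_train_hits = n_train_hits
    )
    dec <- decide_screening(ev)
    dec$n_train <- length(train_idx)
    dec$n_train_hits <- n_train_hits
    ## realize the chosen policy on the remaining compounds
    if (dec$mode == "screen_subset") {
      sets <- assign_label_set(test_pvals$p_active, test_pvals$p_inactive,
                               dec$significance)
      sel <- which(sets == "active")
    } else if (dec$mode == "screen_all") {
      sel <- seq_along(test_idx)
    } else {
      sel <- integer()
    }
    dec$selected_ids <- test$compound_ids[sel]
    dec$realized_test_gain <- realized_gain(
      n_selected = length(sel),
      n_hits = sum(test$labels[sel] == "active"), params = params
    )
    dec$oracle <- oracle_best_gain(test_pvals, test$labels, grid, params)
    dec$regret <- regret_report(dec, dec$oracle)
    dec
  })
  names(decisions) <- sprintf("cost_%g", screen_cost)

  structure(
    list(
      decisions = decisions,
      internal = internal, test_pvals = test_pvals,
      train_idx = train_idx, test_idx = test_idx,
      train_labels = y_train, test_labels = test$labels,
      grid = sort(grid), hit_gain = hit_gain, screen_cost = screen_cost,
      n_iterations = n_iterations, n_trees = n_trees,
      seed = as.integer(seed)
    ),
    class = "iterative_screen"
  )
}

realized_gain <- function(n_selected, n_hits, params) {
  total_gain(0, 0, n_hits, n_selected, params)
}

#' Best achievable gain on the remaining compounds
#'
#' Evaluates every scanned significance level plus the screen-all and
#' screen-none baselines on the *realized* outcomes of the remaining
#' compounds (their true labels) and returns the maximum — the yardstick a
#' decision made from internal validation alone is judged against. Ties
#' are broken as in [decide_screening()].
#'
#' @param test_pvals aggregated p-value table for the remaining compounds.
#' @param truth their true labels.
#' @param grid significance levels to scan.
#' @param params a [gain_cost_params()].
#' @return A list with `mode`, `significance` (or `NA`), `gain`, and the
#'   full per-policy `table` of realized gains.
#' @export
oracle_best_gain <- function(test_pvals, truth,
                             grid = c(0.1, 0.2, 0.3, 0.4),
                             params = gain_cost_params()) {
  truth <- as_activity_factor(truth)
  n_test <- length(truth)
  rows <- lapply(sort(grid), function(eps) {
    sets <- assign_label_set(test_pvals$p_active, test_pvals$p_inactive, eps)
    sel <- !is.na(sets) & sets == "active"
    data.frame(
      policy = sprintf("level_%g", eps), significance = eps,
      n_screened = sum(sel), n_hits = sum(sel & truth == "active"),
      gain = realized_gain(sum(sel), sum(sel & truth == "active"), params),
      stringsAsFactors = FALSE
    )
  })
  tab <- rbind(
    do.call(rbind, rows),
    data.frame(policy = "screen_all", significance = NA_real_,
               n_screened = n_test, n_hits = sum(truth == "active"),
               gain = realized_gain(n_test, sum(truth == "active"), params),
               stringsAsFactors = FALSE),
    data.frame(policy = "screen_none", significance = NA_real_,
               n_screened = 0L, n_hits = 0L, gain = 0,
               stringsAsFactors = FALSE)
  )
  if (all(tab$gain <= 0)) {
    ## nothing beats not screening: the oracle stops
    best <- tab[tab$policy == "screen_none", ]
  } else {
    sig_rank <- ifelse(is.na(tab$significance), Inf, tab$significance)
    ord <- order(-tab$gain, sig_rank, tab$n_screened)
    best <- tab[ord[1L], ]
  }
  list(
    mode = switch(best$policy, screen_all = "screen_all",
                  screen_none = "stop", "screen_subset"),
    significance = best$significance,
    gain = best$gain,
    table = tab
  )
}

#' Regret of a screening decision against the oracle best
#'
#' Reports the realized shortfall of the chosen policy as a percentage of
#' the total gain (initial screen included) the oracle-best policy would
#' have achieved. When that total is non-positive a percentage is
#' meaningless, so the absolute shortfall is reported instead and flagged.
#'
#' @param decision a [decide_screening()] decision carrying
#'   `realized_test_gain`, `n_train` and `n_train_hits`.
#' @param oracle the result of [oracle_best_gain()].
#' @return A list with `percent_loss` (or `NA` under the fallback),
#'   `absolute_loss`, `oracle_gain`, `realized_gain`, and
#'   `fallback_absolute`.
#' @export
regret_report <- function(decision, oracle) {
  if (is.null(decision$realized_test_gain)) {
    stop("decision carries no realized gain; run the workflow in benchmark mode",
         call. = FALSE)
  }
  params <- decision$params
  oracle_total <- oracle$gain +
    params$hit_gain * decision$n_train_hits -
    params$screen_cost * decision$n_train
  abs_loss <- oracle$gain - decision$realized_test_gain
  if (oracle_total > 0) {
    list(percent_loss = 100 * abs_loss / abs(oracle_total),
         absolute_loss = abs_loss, oracle_gain = oracle$gain,
         realized_gain = decision$realized_test_gain,
         fallback_absolute = FALSE)
  } else {
    list(percent_loss = NA_real_, absolute_loss = abs_loss,
         oracle_gain = oracle$gain,
         realized_gain = decision$realized_test_gain,
         fallback_absolute = TRUE)
  }
}

#' @export
print.iterative_screen <- function(x, ...) {
  cat(sprintf(
    "Iterative screen: %d compounds screened initially (%d hits), %d remaining\n",
    length(x$train_idx), sum(x$train_labels == "active"), length(x$test_idx)
  ))
  cat(sprintf("  ACP: %d iterations x %d trees; grid: %s; hit gain %g\n",
              x$n_iterations, x$n_trees,
              paste(x$grid, collapse = ", "), x$hit_gain))
  for (nm in names(x$decisions)) {
    d <- x$decisions[[nm]]
    cat(sprintf("-- screening cost %g --\n", d$params$screen_cost))
    print(d)
    cat(sprintf("  oracle best: %s (gain %.1f)\n", d$oracle$mode,
                d$oracle$gain))
  }
  invisible(x)
}

#' Summary metrics of an iterative screen
#'
#' @param object an [iterative_screen()] result.
#' @param ... unused.
#' @return A data frame of per-level conformal metrics, computed on the
#'   internal validation and on the remaining (test) compounds.
#' @export
summary.iterative_screen <- function(object, ...) {
  rows <- lapply(object$grid, function(eps) {
    rbind(
      cbind(split = "internal",
            conformal_metrics(object$internal, object$internal$truth, eps)),
      cbind(split = "test",
            conformal_metrics(object$test_pvals, object$test_labels, eps))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot estimated and realized gain against confidence level
#'
#' Draws, for each screening cost, the gain estimated from internal
#' validation (solid) and the realized gain on the remaining compounds
#' (dashed) across the scanned confidence levels, with the screen-all
#' policy shown as horizontal reference lines. Agreement between the two
#' curves is what makes the internal scan a trustworthy basis for the
#' screening decision.
#'
#' @param x an [iterative_screen()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.iterative_screen <- function(x, ...) {
  conf <- 100 * (1 - x$grid)
  k <- length(x$decisions)
  old <- graphics::par(mfrow = c(1, k), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (nm in names(x$decisions)) {
    d <- x$decisions[[nm]]
    ev <- d$evaluations
    est <- ev$estimated_test_gain[grepl("^level_", ev$policy)]
    real <- d$oracle$table$gain[grepl("^level_", d$oracle$table$policy)]
    ylim <- range(c(est, real, 0))
    graphics::matplot(conf, cbind(est, real), type = "b", lty = c(1, 2),
                      pch = c(16, 1), col = c("black", "grey40"),
                      xlab = "confidence level (%)", ylab = "test-side gain",
                      main = sprintf("cost %g", d$params$screen_cost),
                      ylim = ylim, ...)
    graphics::abline(h = 0, col = "grey80")
    graphics::abline(
      h = ev$estimated_test_gain[ev$policy == "screen_all"],
      lty = 3
    )
    graphics::legend("bottomright", bty = "n", cex = 0.8,
                     legend = c("internal estimate", "realized",
                                "screen all (est.)"),
                     lty = c(1, 2, 3), pch = c(16, 1, NA),
                     col = c("black", "grey40", "black"))
  }
  invisible(x)
}
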