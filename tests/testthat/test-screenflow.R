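test_that("the workflow is reproducible from its seed", {
  lib <- tiny_library(n = 400, hit_rate = 0.15)
  run1 <- iterative_screen(lib, n_iterations = 4, n_trees = 30,
                           screen_cost = 10, seed = 6)
  run2 <- iterative_screen(lib, n_iterations = 4, n_trees = 30,
                           screen_cost = 10, seed = 6)
  expect_identical(run1$train_idx, run2$train_idx)
  expect_identical(run1$test_pvals, run2$test_pvals)
  expect_identical(run1$decisions$cost_10$mode, run2$decisions$cost_10$mode)
  expect_identical(run1$decisions$cost_10$selected_ids,
                   run2$decisions$cost_10$selected_ids)
})

test_that("a class missing from the initial screen raises guidance", {
  lib <- simulate_library(library_spec(
    n_compounds = 100, hit_rate = 0.02, n_features = 8, n_informative = 4,
    effect_size = 0, seed = 2
  ))
  expect_error(
    iterative_screen(lib, initial_fraction = 0.1, n_iterations = 2,
                     n_trees = 10, seed = 1),
    "initial screen|stratified"
  )
})

test_that("subset selections contain only single-label-active compounds", {
  lib <- tiny_library(n = 500, hit_rate = 0.1, effect_size = 2.5)
  run <- iterative_screen(lib, n_iterations = 5, n_trees = 60,
                          screen_cost = 14, hit_gain = 100, seed = 3)
  d <- run$decisions$cost_14
  if (d$mode == "screen_subset") {
    sets <- assign_label_set(run$test_pvals$p_active,
                             run$test_pvals$p_inactive, d$significance)
    sel_sets <- sets[match(d$selected_ids,
                           lib$compound_ids[run$test_idx])]
    expect_true(all(sel_sets == "active"))
  }
  if (d$mode == "stop") expect_length(d$selected_ids, 0)
})

test_that("oracle_best_gain maximises over realized policies", {
  truth <- rep(c("active", "inactive"), c(10, 90))
  p <- gain_cost_params(400, 10)
  # perfect separation: best is screening exactly the actives
  o <- oracle_best_gain(perfect_pvals(truth), truth, params = p)
  expect_equal(o$gain, 10 * (400 - 10))
  expect_equal(o$mode, "screen_subset")
  # a predictor that never selects anything on a hit-poor library
  pv <- data.frame(p_active = rep(0, 100), p_inactive = rep(1, 100))
  truth_poor <- rep(c("active", "inactive"), c(1, 99))
  p_costly <- gain_cost_params(10, 14)
  o2 <- oracle_best_gain(pv, truth_poor, params = p_costly)
  expect_equal(o2$mode, "stop")
  expect_equal(o2$gain, 0)
  # the oracle dominates every policy in its own table
  expect_true(all(o$table$gain <= o$gain))
})

test_that("regret is a percentage of the oracle total with an absolute fallback", {
  dec <- structure(list(realized_test_gain = 98, n_train = 10,
                        n_train_hits = 5,
                        params = gain_cost_params(400, 10)),
                   class = "screening_decision")
  # oracle total = 100 + 5*400 - 10*10 = 2000 > 0
  r <- regret_report(dec, list(gain = 100))
  expect_equal(r$percent_loss, 100 * 2 / 2000)
  expect_false(r$fallback_absolute)
  # decision matching the oracle -> zero regret
  dec$realized_test_gain <- 100
  expect_equal(regret_report(dec, list(gain = 100))$percent_loss, 0)
  # negative oracle total -> absolute loss, flagged
  dec2 <- structure(list(realized_test_gain = -60, n_train = 100,
                         n_train_hits = 0,
                         params = gain_cost_params(400, 10)),
                    class = "screening_decision")
  r2 <- regret_report(dec2, list(gain = -50))
  expect_true(r2$fallback_absolute)
  expect_true(is.na(r2$percent_loss))
  expect_equal(r2$absolute_loss, 10)
})

test_that("realized gain never exceeds the oracle and totals are coherent", {
  lib <- tiny_library(n = 500, hit_rate = 0.12, effect_size = 2)
  run <- iterative_screen(lib, n_iterations = 5, n_trees = 50,
                          screen_cost = c(6, 14), seed = 8)
  for (d in run$decisions) {
    expect_lte(d$realized_test_gain, d$oracle$gain)
    expect_equal(
      d$regret$absolute_loss, d$oracle$gain - d$realized_test_gain
    )
  }
})
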