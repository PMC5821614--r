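test_that("total_gain implements the linear gain-cost function", {
  p <- gain_cost_params(hit_gain = 400, screen_cost = 10)
  expect_equal(total_gain(0, 100, 0, 0, p), -1000)
  expect_equal(total_gain(0, 0, 5, 100, p), 1000)
  expect_error(total_gain(5, 3, 0, 0, p), "exceed")
  expect_error(total_gain(0, -1, 0, 0, p), "nonnegative")
  expect_error(gain_cost_params(hit_gain = 0), "hit_gain")
})

test_that("total_gain matches a per-compound brute-force sum", {
  set.seed(21)
  for (i in 1:1000) {
    p <- gain_cost_params(hit_gain = runif(1, 1, 500),
                          screen_cost = runif(1, 1, 20))
    s_tr <- sample(0:50, 1); h_tr <- sample(0:s_tr, 1)
    s_te <- sample(0:50, 1); h_te <- sample(0:s_te, 1)
    # per-compound: every screened compound costs, every hit gains
    brute <- sum(rep(p$hit_gain, h_tr)) - sum(rep(p$screen_cost, s_tr)) +
      sum(rep(p$hit_gain, h_te)) - sum(rep(p$screen_cost, s_te))
    expect_equal(total_gain(h_tr, s_tr, h_te, s_te, p), brute)
  }
})

test_that("gain is additive over disjoint screened sets", {
  p <- gain_cost_params(400, 14)
  g12 <- total_gain(3, 40, 7, 100, p)
  g1 <- total_gain(1, 15, 2, 60, p)
  g2 <- total_gain(2, 25, 5, 40, p)
  expect_equal(g1 + g2, g12)
})

test_that("the default grid corresponds to confidence levels 90/80/70/60%", {
  truth <- rep(c("active", "inactive"), 50)
  ev <- evaluate_significance_grid(
    perfect_pvals(truth), truth, n_remaining = 1000, n_train = 100,
    n_train_hits = 50
  )
  lv <- ev[grepl("^level_", ev$policy), ]
  expect_equal(lv$significance, c(0.1, 0.2, 0.3, 0.4))
  expect_setequal(ev$policy[!grepl("^level_", ev$policy)],
                  c("screen_all", "screen_none"))
})

test_that("a degenerate both-label predictor selects nothing", {
  truth <- rep(c("active", "inactive"), each = 20)
  pv <- data.frame(p_active = rep(1, 40), p_inactive = rep(1, 40))
  ev <- evaluate_significance_grid(pv, truth, n_remaining = 500,
                                   n_train = 40, n_train_hits = 20)
  lv <- ev[grepl("^level_", ev$policy), ]
  expect_true(all(lv$n_selected_internal == 0))
  expect_true(all(lv$estimated_test_gain == 0))
  # the screen-all baseline is untouched by the predictor
  p <- gain_cost_params()
  expect_equal(ev$estimated_test_gain[ev$policy == "screen_all"],
               500 * (p$hit_gain * 0.5 - p$screen_cost))
})

test_that("a perfectly separating predictor recovers the closed-form gain", {
  hit_rate <- 0.2
  n <- 200
  truth <- rep(c("active", "inactive"), n * c(hit_rate, 1 - hit_rate))
  p <- gain_cost_params(400, 10)
  for (n_remaining in c(500, 2000)) {
    ev <- evaluate_significance_grid(
      perfect_pvals(truth), truth, grid = c(0.1, 0.3), params = p,
      n_remaining = n_remaining, n_train = n, n_train_hits = n * hit_rate
    )
    lv <- ev[grepl("^level_", ev$policy), ]
    # selection = exactly the true actives at any level
    expect_true(all(lv$n_selected_internal == n * hit_rate))
    expect_true(all(lv$n_hits_internal == n * hit_rate))
    expect_equal(lv$estimated_test_gain,
                 rep(n_remaining * hit_rate * (400 - 10), 2))
  }
})

test_that("decisions cover stop, screen-all and subset with documented ties", {
  base <- function(policy, gain, sig = NA_real_, screened = 0) {
    data.frame(policy = policy, significance = sig,
               n_selected_internal = NA, n_hits_internal = NA,
               est_screened_test = screened, est_hits_test = 0,
               estimated_test_gain = gain, estimated_total_gain = gain,
               validity_active = NA, validity_inactive = NA,
               efficiency_active = NA, efficiency_inactive = NA)
  }
  mk <- function(...) {
    ev <- rbind(...)
    attr(ev, "params") <- gain_cost_params(400, 10)
    attr(ev, "n_train") <- 100
    ev
  }
  # all losses -> stop
  ev <- mk(base("level_0.1", -50, 0.1, 10), base("level_0.2", -5, 0.2, 30),
           base("screen_all", -200, screened = 400),
           base("screen_none", 0))
  expect_equal(decide_screening(ev)$mode, "stop")
  # screen-all strictly maximal
  ev <- mk(base("level_0.1", 100, 0.1, 10), base("screen_all", 900,
                                                 screened = 400),
           base("screen_none", 0))
  expect_equal(decide_screening(ev)$mode, "screen_all")
  # tie between two levels -> the lower-significance one wins
  ev <- mk(base("level_0.1", 500, 0.1, 20), base("level_0.3", 500, 0.3, 50),
           base("screen_all", 100, screened = 400), base("screen_none", 0))
  d <- decide_screening(ev)
  expect_equal(d$mode, "screen_subset")
  expect_equal(d$significance, 0.1)
})

test_that("raising the screening cost never flips stop into screen-all", {
  truth <- rep(c("active", "inactive"), c(5, 195))
  set.seed(5)
  pv <- data.frame(p_active = runif(200), p_inactive = runif(200))
  modes <- vapply(c(6, 10, 14, 50, 400), function(cost) {
    ev <- evaluate_significance_grid(
      pv, truth, params = gain_cost_params(400, cost),
      n_remaining = 800, n_train = 200, n_train_hits = 5
    )
    decide_screening(ev)$mode
  }, character(1))
  stopped <- modes == "stop"
  # once stopped, stays stopped as cost rises
  expect_true(all(diff(stopped) >= 0))
})

test_that("an expensive initial screen triggers the low-expected-gain warning", {
  truth <- rep(c("active", "inactive"), each = 50)
  ev <- evaluate_significance_grid(
    perfect_pvals(truth), truth, params = gain_cost_params(400, 14),
    n_remaining = 40, n_train = 5000, n_train_hits = 50
  )
  d <- decide_screening(ev)
  expect_equal(d$mode, "screen_subset")
  # cost of the initial screen (70000) > 5 x estimated subset gain
  expect_gt(14 * 5000, 5 * d$estimated_test_gain)
  expect_match(d$warnings, "five times", all = FALSE)

  # same predictor with a cheap initial screen: no warning
  ev2 <- evaluate_significance_grid(
    perfect_pvals(truth), truth, params = gain_cost_params(400, 14),
    n_remaining = 4000, n_train = 100, n_train_hits = 50
  )
  expect_length(decide_screening(ev2)$warnings, 0)
})
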