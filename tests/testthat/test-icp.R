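test_that("proper/calibration split uses floor(0.7 n) with the rest calibrating", {
  x <- matrix(rnorm(10 * 4), 10)
  y <- rep(c("active", "inactive"), each = 5)
  m <- fit_icp(x, y, n_trees = 20, seed = 3)
  expect_length(m$proper_idx, 7)
  expect_length(m$calib_idx, 3)
  # disjoint and covering
  expect_setequal(c(m$proper_idx, m$calib_idx), 1:10)
  expect_length(intersect(m$proper_idx, m$calib_idx), 0)
})

test_that("different seeds give different partitions", {
  lib <- tiny_library(n = 40)
  parts <- vapply(1:6, function(s) {
    m <- fit_icp(lib, n_trees = 10, seed = s)
    paste(m$proper_idx, collapse = ",")
  }, character(1))
  expect_equal(length(unique(parts)), 6)
})

test_that("degenerate training data is rejected", {
  x <- matrix(rnorm(20 * 3), 20)
  expect_error(fit_icp(x, rep("inactive", 20), n_trees = 10, seed = 1),
               "both classes")
  # one lone active: some seed places it outside the calibration set
  y <- c("active", rep("inactive", 19))
  expect_error(fit_icp(x, y, n_trees = 10, seed = 2), "calibration|proper")
})

test_that("conformity scores are vote fractions in [0,1] summing to 1", {
  lib <- tiny_library(n = 120)
  m <- fit_icp(lib, n_trees = 50, seed = 1)
  sc <- predict(m, lib$features, type = "score")
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)))
  expect_true(all(m$calib_active >= 0 & m$calib_active <= 1))
  expect_equal(m$calib_active, sort(m$calib_active))
  expect_equal(m$calib_inactive, sort(m$calib_inactive))
})

test_that("feature-width mismatch is caught at prediction time", {
  lib <- tiny_library(n = 60)
  m <- fit_icp(lib, n_trees = 10, seed = 1)
  expect_error(predict(m, matrix(0, 2, 5)), "features")
})

test_that("p_value implements the strict-lower fraction with denominator n+1", {
  # nine calibration scores, eight strictly below: position 9 -> 0.80
  cal9 <- c(0.1, 0.2, 0.3, 0.35, 0.4, 0.5, 0.6, 0.7, 0.9)
  expect_equal(p_value(0.75, cal9), 0.80)
  # nothing below: position 1 -> 0.0
  expect_equal(p_value(0.05, cal9), 0)
  # above all n scores -> n/(n+1)
  expect_equal(p_value(0.95, cal9), 9 / 10)
  # ties are not counted as lower
  expect_equal(p_value(0.5, c(0.3, 0.5, 0.5, 0.7)), 1 / 5)
  # smoothed variant counts half of each tie
  expect_equal(p_value(0.5, c(0.3, 0.5, 0.5, 0.7), smoothed = TRUE), 2 / 5)
  expect_error(p_value(0.5, numeric(0)), "empty")
})

test_that("p_value agrees with an explicit counting oracle", {
  set.seed(101)
  for (i in 1:1000) {
    cal <- round(runif(sample(1:30, 1)), 2)
    s <- round(runif(3), 2)
    expect_identical(p_value(s, cal), pval_oracle(s, cal))
  }
})

test_that("label sets cover all four outcomes with a >= rule at the boundary", {
  expect_equal(assign_label_set(0.80, 0.0, 0.20), "active")
  expect_equal(assign_label_set(0.0, 0.80, 0.20), "inactive")
  expect_equal(assign_label_set(0.5, 0.5, 0.20), "both")
  expect_equal(assign_label_set(0.05, 0.1, 0.20), "empty")
  # boundary: p equal to the significance level is included
  expect_equal(assign_label_set(0.20, 0.0, 0.20), "active")
  expect_error(assign_label_set(0.5, 0.5, 0), "significance")
  expect_error(assign_label_set(0.5, 0.5, 1), "significance")
  expect_error(assign_label_set(1.2, 0.5, 0.2), "0, 1")
})

test_that("label sets are nested across significance levels", {
  set.seed(7)
  pa <- runif(300)
  pi_ <- runif(300)
  eps <- sort(runif(6, 0.01, 0.9))
  sets <- vapply(eps, function(e) assign_label_set(pa, pi_, e),
                 character(300))
  contains <- function(set, cls) set == cls | set == "both"
  for (j in seq_len(ncol(sets) - 1)) {
    for (cls in c("active", "inactive")) {
      # larger significance never adds a label
      expect_true(all(!contains(sets[, j + 1], cls) |
                        contains(sets[, j], cls)))
    }
  }
})

test_that("unconditional calibration pools both classes into one list", {
  lib <- tiny_library(n = 150)
  m <- fit_icp(lib, n_trees = 30, mondrian = FALSE, seed = 5)
  expect_identical(m$calib_active, m$calib_inactive)
  expect_length(m$calib_active, length(m$calib_idx))
})
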