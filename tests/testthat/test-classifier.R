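test_that("worked example: thresholds sit at the documented midpoints", {
  values <- c(1, 2, 3, 2.5, 4, 5)
  labels <- c("control", "control", "control", "ige", "ige", "ige")
  tp <- optimize_thresholds(values, labels, "higher_is_ige")
  expect_gt(tp$th1, 3); expect_lt(tp$th1, 4)
  expect_equal(tp$th1, 3.5)
  expect_equal(tp$sens_at_th1, 2 / 3)
  expect_gt(tp$th2, 2); expect_lt(tp$th2, 2.5)
  expect_equal(tp$th2, 2.25)
  expect_equal(tp$spec_at_th2, 2 / 3)
})

test_that("separable cohorts put both thresholds in the gap; degenerate ties give zero", {
  tp <- optimize_thresholds(c(1, 2, 5, 6), c("control", "control", "ige",
                                             "ige"), "higher_is_ige")
  expect_equal(tp$th1, 3.5)
  expect_equal(tp$th2, 3.5)
  expect_equal(tp$sens_at_th1, 1)
  expect_equal(tp$spec_at_th2, 1)
  tpd <- optimize_thresholds(rep(2, 6), rep(c("control", "ige"), 3),
                             "higher_is_ige")
  expect_equal(tpd$sens_at_th1, 0)
  expect_equal(tpd$spec_at_th2, 0)
})

test_that("three-way classification follows the dual-threshold rule", {
  tp <- structure(list(th1 = 3.5, th2 = 2.25, direction = "higher_is_ige"),
                  class = "threshold_pair")
  expect_equal(classify(5, tp), "ige")
  expect_equal(classify(3.0, tp), "uncertain")
  expect_equal(classify(1.0, tp), "normal")
  # lower_is_ige mirrors through orientation
  vals <- c(9, 10, 11, 8, 7.5, 7)
  labs <- c(rep("control", 3), rep("ige", 3))
  tpl <- optimize_thresholds(vals, labs, "lower_is_ige")
  expect_equal(classify(6.5, tpl), "ige")
  expect_equal(classify(12, tpl), "normal")
})

test_that("training-set guarantees hold and midpoints match the scan oracle", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    is_ige <- c(rep(FALSE, floor(n / 2)), rep(TRUE, ceiling(n / 2)))
    values <- round(rnorm(n, mean = ifelse(is_ige, 1, 0)), 2)
    labels <- ifelse(is_ige, "ige", "control")
    tp <- optimize_thresholds(values, labels, "higher_is_ige")
    # guarantee: zero training false positives at th1, none missed at th2
    expect_equal(sum(values[!is_ige] > tp$th1), 0L)
    expect_equal(sum(values[is_ige] < tp$th2), 0L)
    oracle <- scan_oracle(values, is_ige)
    expect_equal(tp$sens_at_th1, oracle$sens_at_spec1)
    expect_equal(tp$spec_at_th2, oracle$spec_at_sens1)
  }
})

test_that("LOOCV handles degenerate and separable cohorts", {
  same <- loocv_classify(rep(1, 8), rep(c("ige", "control"), 4))
  expect_true(all(same$folds$outcome == "uncertain"))
  vals <- c(1, 1.5, 2, 2.2, 7, 8, 9, 9.5)
  labs <- c(rep("control", 4), rep("ige", 4))
  sep <- loocv_classify(vals, labs)
  expect_true(all(sep$folds$outcome[labs == "ige"] == "ige"))
  expect_true(all(sep$folds$outcome[labs == "control"] == "normal"))
  p <- performance(sep)
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 1)
})

test_that("LOOCV outcomes are invariant to subject ordering", {
  set.seed(123)
  vals <- rnorm(12, mean = rep(c(0, 1.2), each = 6))
  labs <- rep(c("control", "ige"), each = 6)
  base <- loocv_classify(vals, labs)
  perm <- sample(12)
  shuffled <- loocv_classify(vals[perm], labs[perm])
  expect_equal(shuffled$folds$outcome[order(perm)], base$folds$outcome)
})

test_that("cached-table path agrees with the plain-vector path", {
  set.seed(5)
  vals <- rnorm(10, mean = rep(c(0, 1.5), each = 5))
  labs <- rep(c("control", "ige"), each = 5)
  tab <- array(vals, dim = c(10, 1, 1),
               dimnames = list(NULL, "O1", "K1"))
  attr(tab, "Kgrid") <- 1
  class(tab) <- "local_coupling_table"
  plain <- loocv_classify(vals, labs)
  cached <- loocv_classify(tab, labs)
  expect_equal(cached$folds$outcome, plain$folds$outcome)
})

test_that("grid LOOCV optimizes the two objectives independently", {
  # channel A separates at 100% specificity, channel B at 100% sensitivity
  set.seed(9)
  n <- 12
  labs <- rep(c("control", "ige"), each = 6)
  a <- rep(0, n)                           # uninformative
  b <- c(rnorm(6, 0), rnorm(6, 3))         # strong
  tab <- array(c(a, b), dim = c(n, 2, 1),
               dimnames = list(NULL, c("A", "B"), "K1"))
  attr(tab, "Kgrid") <- 1
  res <- loocv_classify(tab, labs)
  # the strong channel should be selected in every fold for both objectives
  expect_true(all(res$folds$channel1 == "B"))
  expect_true(all(res$folds$channel2 == "B"))
  p <- performance(res)
  expect_gt(p$sensitivity, 0.5)
})

test_that("performance reduces count tables to the published rates", {
  counts <- rbind(ige = c(ige = 17, uncertain = 10, normal = 3),
                  control = c(ige = 0, uncertain = 13, normal = 25))
  p <- performance(counts)
  expect_equal(round(100 * p$sensitivity, 1), 56.7)
  expect_equal(round(100 * p$specificity, 1), 65.8)
  all_unc <- rbind(ige = c(0, 30, 0), control = c(0, 38, 0))
  p0 <- performance(all_unc)
  expect_equal(p0$sensitivity, 0)
  expect_equal(p0$specificity, 0)
})
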