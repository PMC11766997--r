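test_that("r-squared follows the sensor-mean convention by default", {
  p <- paired_sample(sensor = c(1.1, 1.9, 3.0), measured = c(1, 2, 3))
  # SSres = 0.02; sensor mean 2.0 gives SStot = 2
  expect_equal(r_squared(p), 1 - 0.02 / 2)

  ident <- paired_sample(1:5, 1:5)
  expect_equal(r_squared(ident), 1)
  expect_equal(r_squared(ident, denominator = "measured-mean"), 1)

  const <- paired_sample(c(1, 2, 3), c(2, 2, 2))
  expect_error(r_squared(const, denominator = "measured-mean"), "zero total")
})

test_that("error metrics and their identity", {
  p <- paired_sample(c(1.1, 0.9), c(1, 1)) # d = +0.1, -0.1
  em <- error_metrics(p)
  expect_equal(em$rmse, 0.1)
  expect_equal(em$mae, 0.1)
  expect_equal(em$bias, 0)

  ident <- error_metrics(paired_sample(1:4, 1:4))
  expect_equal(unlist(ident[c("rmse", "mae", "bias")]),
               c(rmse = 0, mae = 0, bias = 0))

  # RMSE^2 = bias^2 + ((n-1)/n) s_d^2 and MAE >= |bias| on random input
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:30, 1)
    em <- error_metrics(paired_sample(rnorm(n, 1), rnorm(n)))
    expect_equal(em$rmse^2, em$bias^2 + (n - 1) / n * em$s_d^2,
                 tolerance = 1e-12)
    expect_gte(em$mae, abs(em$bias) - 1e-15)
  }
})

test_that("mean-difference CI behaves as a paired-t interval", {
  expect_equal(unname(ci_from_summary(0.5, 0, 6)), c(0.5, 0.5))

  p <- paired_sample(c(1, 2, 3, 5), c(1.2, 1.9, 3.3, 4.8))
  widths <- vapply(c(0.5, 0.8, 0.95, 0.99),
                   function(cl) diff(mean_difference_ci(p, cl)), numeric(1))
  expect_true(all(diff(widths) > 0))
  ci <- mean_difference_ci(p)
  d <- p$x - p$y
  expect_equal(mean(ci), mean(d)) # symmetric about the bias
})

test_that("CCC has the documented closed forms and bounds", {
  expect_equal(concordance_ccc(paired_sample(1:5, 1:5)), 1)
  # unit shift with perfect correlation: 2*(2/3) / (2/3 + 2/3 + 1) = 4/7
  expect_equal(concordance_ccc(paired_sample(c(1, 2, 3), c(2, 3, 4))), 4 / 7)

  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(10); y <- 0.5 * x + rnorm(10)
    ccc <- concordance_ccc(paired_sample(x, y))
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
    expect_lte(abs(ccc), 1)
  }
  expect_error(concordance_ccc(paired_sample(c(1, 1, 1), c(1, 2, 3))),
               "zero variance")
  # sample-variance mode shrinks the mean-shift penalty's relative weight
  p <- paired_sample(c(1, 2, 3), c(2, 3, 4))
  expect_gt(concordance_ccc(p, variance = "sample"), concordance_ccc(p))
})

test_that("paired t statistic and two-sided p-value", {
  p <- paired_sample(c(1, 2, 3, 4), c(1.1, 2.0, 3.2, 4.1))
  tt <- paired_t_test(p)
  expect_equal(tt$t, -2.449, tolerance = 1e-3)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), 3))

  expect_error(paired_t_test(paired_sample(2:6, 1:5)), "zero-variance")

  # p matches the regularized incomplete-beta closed form
  for (t in c(-3.49, -1.44, 0.7, 2.19, 5)) {
    for (df in c(2, 5, 11)) {
      expect_equal(t_p_value(t, df), pbeta(df / (df + t^2), df / 2, 0.5),
                   tolerance = 1e-10)
    }
  }
})

test_that("agreement report equals the individually computed statistics", {
  set.seed(12)
  x <- rnorm(20, 10, 2); y <- x + rnorm(20, -0.1, 0.3)
  p <- paired_sample(x, y, units = "m")
  rep <- agreement_report(p, metric = "height")
  em <- error_metrics(p)
  expect_equal(rep$rmse, em$rmse)
  expect_equal(rep$mae, em$mae)
  expect_equal(rep$bias, em$bias)
  expect_equal(rep$r_squared, r_squared(p))
  expect_equal(rep$ccc, concordance_ccc(p))
  expect_equal(rep$ci, mean_difference_ci(p))
  expect_equal(rep$t, paired_t_test(p)$t)
  expect_equal(rep$p_value, paired_t_test(p)$p)
  expect_output(print(rep), "Agreement report: height")

  perfect <- agreement_report(paired_sample(1:6, 1:6))
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$ccc, 1)
  expect_equal(unname(perfect$ci), c(0, 0))
})
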