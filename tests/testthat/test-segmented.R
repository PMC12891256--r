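test_that("noiseless segmented data are recovered exactly", {
  set.seed(1)
  x <- runif(300, 5, 30)
  y <- 10 + 0.5 * x + (1.5 - 0.5) * pmax(x - 17, 0)
  m <- fit_segmented(x, y, init_breakpoint = 15.5)
  expect_equal(m$intercept, 10, tolerance = 1e-6)
  expect_equal(m$slope1, 0.5, tolerance = 1e-6)
  expect_equal(m$breakpoint, 17, tolerance = 1e-6)
  expect_equal(m$slope2, 1.5, tolerance = 1e-6)
  expect_equal(m$mae_dB, 0, tolerance = 1e-8)
  expect_equal(m$rmse_dB, 0, tolerance = 1e-8)
})

test_that("purely linear noiseless data give equal slopes", {
  set.seed(2)
  x <- runif(100, 0, 30)
  y <- 3 + 0.7 * x
  m <- fit_segmented(x, y)
  expect_equal(m$slope1, m$slope2, tolerance = 1e-6)
  expect_equal(m$slope1, 0.7, tolerance = 1e-6)
})

test_that("fitted breakpoint matches the exhaustive grid oracle", {
  set.seed(101)
  for (i in 1:5) {
    x <- runif(200, 5, 30)
    y <- 12 + 0.6 * x + 0.7 * pmax(x - 16, 0) + rnorm(200, 0, 2)
    m <- fit_segmented(x, y)
    g <- grid_search_breakpoint(x, y)
    # agreement within the grid step, except where the continuous optimum
    # strictly beats the grid over a near-tied rival basin
    expect_true(abs(m$breakpoint - g$breakpoint) <= 0.01 ||
                  m$rss <= g$rss + 1e-9)
    expect_lte(m$rss, g$rss + 1e-8)
  }
})

test_that("segmented fit never exceeds the simple linear fit's RSS", {
  set.seed(8)
  for (i in 1:10) {
    x <- runif(60, 0, 30)
    y <- rnorm(60, 15 + 0.2 * x, 3)
    m <- fit_segmented(x, y)
    rss_lin <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
    expect_lte(m$rss, rss_lin + 1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_segmented(rep(10, 50), rnorm(50)), "degenerate")
  expect_error(fit_segmented(1:5, 1:5), "at least 10")
})

test_that("breakpoint recovery across noisy replicates is accurate", {
  set.seed(33)
  errs <- replicate(60, {
    x <- runif(300, 5, 30)
    y <- 10 + 0.5 * x + 1.0 * pmax(x - 17, 0) + rnorm(300, 0, 2)
    m <- fit_segmented(x, y)
    expect_gt(m$slope1, 0); expect_gt(m$slope2, m$slope1)
    abs(m$breakpoint - 17)
  })
  expect_lt(median(errs), 1)
})

test_that("Davies test rejects strong kinks and respects invariances", {
  set.seed(4)
  x <- runif(100, 0, 30)
  y <- 5 + 0.2 * x + 2 * pmax(x - 15, 0) + rnorm(100, 0, 0.5)
  d <- davies_test(x, y)
  expect_lt(d$p_value, 1e-6)
  # affine rescaling of y leaves the p-value unchanged
  d2 <- davies_test(x, 3 + 10 * y)
  expect_equal(d$p_value, d2$p_value, tolerance = 1e-10)
  expect_error(davies_test(x[1:10], y[1:10]), "at least 20")
  expect_error(davies_test(x, y, k = 1), "candidate")
})

test_that("extra-sum-of-squares F matches hand computation", {
  set.seed(6)
  # two strata with different generating slopes
  x1 <- runif(40, 5, 30); y1 <- 5 + 0.4 * x1 + 0.5 * pmax(x1 - 15, 0) + rnorm(40, 0, 1)
  x2 <- runif(40, 5, 30); y2 <- 9 + 0.9 * x2 + 0.7 * pmax(x2 - 18, 0) + rnorm(40, 0, 1)
  m1 <- fit_segmented(x1, y1); m2 <- fit_segmented(x2, y2)
  pooled <- fit_segmented(c(x1, x2), c(y1, y2))
  res <- compare_nested_f(list(m1, m2), pooled)
  rss_sub <- m1$rss + m2$rss
  f_hand <- ((pooled$rss - rss_sub) / 4) / (rss_sub / (80 - 8))
  expect_equal(res$f, f_hand, tolerance = 1e-10)
  expect_equal(res$df1, 4); expect_equal(res$df2, 72)
  expect_equal(res$p_value, pf(f_hand, 4, 72, lower.tail = FALSE))

  # identical generating models, noiseless: F ~ 0
  xa <- runif(30, 5, 30); xb <- runif(30, 5, 30)
  f0 <- function(x) 5 + 0.4 * x + 0.5 * pmax(x - 15, 0)
  ma <- suppressWarnings(fit_segmented(xa, f0(xa)))
  mb <- suppressWarnings(fit_segmented(xb, f0(xb)))
  mp <- suppressWarnings(fit_segmented(c(xa, xb), f0(c(xa, xb))))
  expect_lt(compare_nested_f(list(ma, mb), mp)$f, 1e-6)
})

test_that("stratified fits beat the pooled fit when slopes truly differ", {
  set.seed(12)
  hits <- replicate(20, {
    x1 <- runif(250, 5, 30); y1 <- 5 + 0.3 * x1 + rnorm(250, 0, 2)
    x2 <- runif(250, 5, 30); y2 <- 20 + 0.9 * x2 + rnorm(250, 0, 2)
    # linear strata have no breakpoint, so the grid-fallback warning is expected
    res <- suppressWarnings(compare_nested_f(
      list(fit_segmented(x1, y1), fit_segmented(x2, y2)),
      fit_segmented(c(x1, x2), c(y1, y2))))
    res$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("prediction errors follow their definitions", {
  m <- structure(list(intercept = 0, slope1 = 1, breakpoint = 10, slope2 = 1),
                 class = "segmented_model")
  x <- c(1, 2, 3, 4)
  expect_equal(prediction_errors(m, x, x), list(mae_dB = 0, rmse_dB = 0))
  y <- x + c(1, -1, 1, -1)
  pe <- prediction_errors(m, x, y)
  expect_equal(pe$mae_dB, 1); expect_equal(pe$rmse_dB, 1)
  set.seed(5)
  for (i in 1:10) {
    yy <- x + rnorm(4)
    pe <- prediction_errors(m, x, yy)
    expect_gte(pe$rmse_dB, pe$mae_dB)
  }
  expect_error(prediction_errors(m, numeric(0), numeric(0)), "no finite")
})

test_that("model divergence equals the brute-force scan", {
  m1 <- structure(list(intercept = 5, slope1 = 0.5, breakpoint = 15, slope2 = 1.2),
                  class = "segmented_model")
  m2 <- structure(list(intercept = 9, slope1 = 0.7, breakpoint = 18, slope2 = 0.3),
                  class = "segmented_model")
  expect_equal(max_model_divergence(list(m1, m1), c(5, 30)), 0)
  off <- m1; off$intercept <- m1$intercept + 2.5
  expect_equal(max_model_divergence(list(m1, off), c(5, 30)), 2.5)
  xs <- seq(5, 30, by = 0.001)
  brute <- max(abs(predict(m1, xs) - predict(m2, xs)))
  expect_equal(max_model_divergence(list(m1, m2), c(5, 30)), brute)
})
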