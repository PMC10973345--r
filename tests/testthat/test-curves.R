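test_that("polynomial curves evaluate ascending-power coefficients", {
  crv <- polynomial_curve(c(2, 1), domain = c(0, 10))
  expect_equal(predict(crv, c(0, 5)), c(2, 7))
  expect_equal(crv$degree, 1L)
  expect_error(predict(crv, 20, strict = TRUE), "domain")
  expect_equal(predict(crv, 20), 22)  # extrapolation allowed by default
})

test_that("cross-validated MSE is zero for interpolable noiseless data", {
  x <- 1:12
  y <- 3 + 2 * x
  expect_equal(cv_mse(x, y, degree = 1, seed = 1), 0, tolerance = 1e-18)
})

test_that("cross-validation prefers the generating degree under small noise", {
  set.seed(5)
  x <- seq(4, 41, length.out = 12)
  y <- 50 - 0.5 * x + 0.01 * x^3 / 10 + rnorm(12, 0, 0.1)
  m1 <- cv_mse(x, y, degree = 1, seed = 11)
  m3 <- cv_mse(x, y, degree = 3, seed = 11)
  expect_lt(m3, m1)
  # determinism under a shared fold seed
  expect_identical(cv_mse(x, y, 3, seed = 11), cv_mse(x, y, 3, seed = 11))
})

test_that("modal degree selection is unanimous on noiseless low-degree data", {
  x <- seq(4, 41, length.out = 11)
  y <- 2 + x
  sel <- select_degree(x, y, degree_search_config(seed = 3))
  expect_equal(sel$degree, 1L)
  expect_equal(unname(sel$frequency["1"]), 1000L)
  expect_equal(sum(sel$frequency), 1000L)
})

test_that("select_degree with one repeat equals a single CV argmin", {
  set.seed(17)
  x <- seq(4, 41, length.out = 11)
  y <- predict(canonical_median_curve(), x) + rnorm(11, 0, 0.5)
  cfg <- degree_search_config(repeats = 1L, seed = 23)
  sel <- select_degree(x, y, cfg)
  mse <- cv_mse(x, y, degree = 1:5, k_folds = 3, seed = 23)  # same partition
  expect_equal(sel$degree, (1:5)[which.min(mse)])
})

test_that("least-squares fits interpolate and recover published coefficients", {
  line <- fit_polynomial(c(1, 4), c(2, 8), 1)
  expect_equal(predict(line, c(1, 4)), c(2, 8))

  # five points determine the degree-4 median curve exactly
  x <- c(4, 13, 22, 31, 41)
  y <- predict(canonical_median_curve(), x)
  fit <- fit_polynomial(x, y, 4)
  expect_equal(fit$coefficients, c(56.7, -0.223, -0.113, 0.00545, -0.0000653),
               tolerance = 1e-5)

  expect_error(fit_polynomial(c(1, 1, 2, 3, 4), c(1, 2, 3, 4, 5), 4), "rank")
  expect_error(fit_polynomial(1:3, 1:3, 3), "degree \\+ 1")
})

test_that("OLS residuals are orthogonal to the design columns", {
  set.seed(21)
  x <- seq(4, 41, length.out = 12)
  y <- 45 + 0.2 * x + rnorm(12)
  fit <- fit_polynomial(x, y, 2)
  r <- y - predict(fit, x)
  xmat <- outer(x, 0:2, `^`)
  expect_equal(max(abs(crossprod(xmat, r))), 0, tolerance = 1e-6)
})

test_that("a noisy sample of the degree-4 curve is usually assigned degree 4", {
  x <- seq(5.5, 40, length.out = 11)
  truth <- predict(canonical_median_curve(), x)
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    y <- truth + rnorm(11, 0, 0.3)
    sel <- select_degree(x, y, degree_search_config(seed = s, repeats = 200))
    hits <- hits + (sel$degree == 4L)
  }
  expect_gte(hits, 8L)
})

test_that("smoothed limits preserve percentile ordering week by week", {
  pl <- default_pipeline()
  gw <- 4:41
  lower <- predict(pl$scr_curves$p2.5, gw)
  med <- predict(pl$scr_curves$p50, gw)
  upper <- predict(pl$scr_curves$p97.5, gw)
  expect_true(all(lower < med))
  expect_true(all(med < upper))
  # degree-search bookkeeping is attached
  ds <- attr(pl$scr_curves, "degree_search")
  expect_true(all(vapply(ds, sum, numeric(1)) == 1000))
})

test_that("smooth_limits refuses too few periods and flags failures", {
  pl <- default_pipeline()
  expect_error(smooth_limits(pl$scr_ris[1:4]), "at least 6")
  # the default synthetic run fails coverage confirmation: 'full' must stop
  expect_error(smooth_limits(pl$scr_ris, percentiles = 50,
                             cfg = degree_search_config(repeats = 5),
                             require = "full"),
               "coverage")
})
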