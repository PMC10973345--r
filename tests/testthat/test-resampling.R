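test_that("resampled means never leave the range of the original data", {
  for (s in 1:10) {
    set.seed(s)
    x <- 40 + rexp(50, 1 / 5)
    v <- resample_period(x, resample_config(seed = s))
    expect_length(v, 120L)
    expect_true(all(v >= min(x) & v <= max(x)))
  }
})

test_that("degenerate periods resample to enumerable means", {
  expect_equal(resample_period(rep(7, 30)), rep(7, 120))
  v <- resample_period(c(2, 10), resample_config(seed = 4))
  expect_true(all(v %in% c(2, 6, 10)))
  # without replacement within one pair of a 2-value GP: always the mean
  expect_true(all(v == 6))
})

test_that("mean-of-two resampling halves the variance", {
  set.seed(12)
  x <- rnorm(5000, 50, 3)
  v <- resample_period(x, resample_config(t_iter = 10000, seed = 1))
  expect_equal(var(v), var(x) / 2, tolerance = 0.05)
})

test_that("resampling is deterministic and validates its inputs", {
  x <- rnorm(30, 50, 5)
  cfg <- resample_config(seed = 77)
  expect_identical(resample_period(x, cfg), resample_period(x, cfg))
  expect_error(resample_period(1, cfg), "insufficient")
  expect_error(resample_config(n_pick = 1), "n_pick")
  expect_error(resample_config(t_iter = 30), "t_iter")
})

test_that("the Gaussian screen separates normal from non-normal samples", {
  set.seed(2024)
  v <- rnorm(120)
  d <- check_gaussian(v)
  expect_true(d$pass)
  expect_true(d$kurtosis >= 2.5 && d$kurtosis <= 3.5)
  expect_true(abs(d$skewness) <= 0.5)
  expect_gte(d$shapiro_p, 0.05)

  set.seed(99)
  e <- check_gaussian(rexp(120))  # population skewness 2, far outside [-0.5, 0.5]
  expect_false(e$pass)
  expect_gt(e$skewness, 0.5)

  z <- check_gaussian(rep(5, 120))
  expect_false(z$pass)
  expect_equal(z$reason, "zero variance")
  expect_error(check_gaussian(c(1, 2)), "at least 3")
})

test_that("the 95% interval uses the ceil(0.025 t) order-statistic rule", {
  expect_equal(ci_ranks(120), c(lower = 3L, upper = 118L))
  expect_equal(ci_ranks(40), c(lower = 1L, upper = 40L))
  expect_equal(ci_ranks(200), c(lower = 5L, upper = 196L))
  expect_error(ci_ranks(39), ">= 40")

  expect_equal(ci_from_resamples(as.numeric(1:120)),
               c(lower = 3, upper = 118))
  expect_equal(ci_from_resamples(as.numeric(1:40)), c(lower = 1, upper = 40))
  expect_error(ci_from_resamples(c(3, 2, 1, rep(4, 117))), "sorted")
  expect_error(ci_from_resamples(1:100, t_iter = 120), "expected 120")
  # all-equal values give a degenerate (invalid downstream) interval
  ci <- ci_from_resamples(rep(5, 120))
  expect_equal(unname(ci), c(5, 5))
})

test_that("coverage verification applies the closed-interval 95% rule", {
  full <- verify_coverage(1:50, 0, 100)
  expect_equal(full$coverage, 1)
  expect_true(full$pass)

  x <- c(seq_len(94), 200 + seq_len(6))  # 94 of 100 inside
  just_miss <- verify_coverage(x, 0, 100)
  expect_equal(just_miss$coverage, 0.94)
  expect_false(just_miss$pass)

  y <- c(seq_len(19), 500)  # 19 of 20 inside: exactly 95%
  boundary <- verify_coverage(y, 1, 19)  # closed: both endpoints count
  expect_equal(boundary$coverage, 0.95)
  expect_true(boundary$pass)

  expect_error(verify_coverage(numeric(0), 0, 1), "empty")
  expect_error(verify_coverage(1:10, 5, 5), "lower")
})

test_that("build_period_ri accepts a well-behaved Gaussian period quickly", {
  set.seed(31)
  gp <- rnorm(200, 50, 5)
  rs <- build_period_ri(gp, resample_config(seed = 31, max_attempts = 100))
  expect_s3_class(rs, "resample_set")
  expect_true(rs$gaussian_pass)
  expect_true(rs$ci_lower > 30 && rs$ci_upper < 70)
  expect_false(is.unsorted(rs$values))
  # accepted implies the full criteria, whatever the outcome was
  if (rs$accepted) {
    expect_true(rs$coverage >= 0.95)
    expect_true(rs$diagnostics$kurtosis >= 2.5 && rs$diagnostics$kurtosis <= 3.5)
  }
})

test_that("build_period_ri never accepts a zero-variance period", {
  rs <- build_period_ri(rep(5, 20), resample_config(seed = 1, max_attempts = 5))
  expect_false(rs$accepted)
  expect_false(rs$gaussian_pass)
  expect_equal(rs$attempts_used, 5L)
})

test_that("build_period_ri is fully deterministic including retries", {
  set.seed(6)
  x <- 40 + rexp(80, 1 / 6)
  cfg <- resample_config(seed = 202, max_attempts = 30)
  a <- build_period_ri(x, cfg)
  b <- build_period_ri(x, cfg)
  expect_identical(a, b)
})

test_that("resample_percentile generalises the interval rank rule", {
  rs <- list(values = as.numeric(1:120))
  expect_equal(resample_percentile(rs, 2.5), 3)
  expect_equal(resample_percentile(rs, 97.5), 118)
  expect_equal(resample_percentile(rs, 50), 60)
  expect_equal(resample_percentile(rs, 75), 91)
  expect_equal(resample_percentile(rs, 95), 115)
})
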