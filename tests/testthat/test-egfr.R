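test_that("hyperfiltration gap and ratios obey their algebraic identities", {
  expect_equal(hyperfiltration_gap(55.25, 55.25), 0)
  expect_equal(hyperfiltration_gap(55.25, 40), 15.25)
  expect_equal(overall_hyperfiltration_ratio(55.25, 55.25), 1)
  expect_equal(overall_hyperfiltration_ratio(55.25, 110.5), 0)
  expect_equal(overall_hyperfiltration_ratio(55.25, 40), 2 - 40 / 55.25)
  expect_equal(overall_hyperfiltration_ratio(55.25, 40), 1.27602,
               tolerance = 1e-5)

  set.seed(14)
  bsc <- runif(50, 40, 70)
  scr <- runif(50, 25, 100)
  expect_equal(hyperfiltration_gap(bsc, scr) + scr, bsc)
  expect_equal(overall_hyperfiltration_ratio(bsc, scr) - 1,
               simple_hyperfiltration_gap_ratio(bsc, scr))
  expect_error(hyperfiltration_gap(-1, 40), "> 0")
})

test_that("k_gw is the baseline over the median curve, maximal at the nadir", {
  params <- egfr_parameters()
  expect_equal(predict(params$median_curve, 22), 39.8367, tolerance = 1e-4)
  expect_equal(k_gw(22), 55.25 / predict(canonical_median_curve(), 22))
  expect_equal(k_gw(22), 1.38691, tolerance = 1e-5)
  gw <- 4:41
  expect_true((which.max(k_gw(gw)) + 3L) %in% c(22L, 23L))
  expect_equal(which.min(predict(params$median_curve, gw)) + 3,
               which.max(k_gw(gw)) + 3)
  expect_error(k_gw(2), "pre-implantation")
})

test_that("the gestational eGFR formula reproduces hand-computed values", {
  # at baseline SCr the ratio is exactly 1
  expect_equal(gestational_egfr(55.25, 22), 103.1 * k_gw(22))
  expect_equal(gestational_egfr(55.25, 22), 142.99, tolerance = 1e-4)
  # full evaluation at SCr 40, GW 20 (median curve value 40.192)
  expect_equal(predict(canonical_median_curve(), 20), 40.192, tolerance = 1e-4)
  expect_equal(gestational_egfr(40, 20),
               (2 - 40 / 55.25) * 103.1 * 55.25 / 40.192, tolerance = 1e-5)
  expect_equal(gestational_egfr(40, 20), 180.846, tolerance = 1e-4)
})

test_that("eGFR is affine, strictly decreasing in SCr, zero at twice baseline", {
  for (gw in c(4, 12, 22, 33, 41)) {
    scr <- seq(20, 100, by = 5)
    e <- gestational_egfr(scr, gw)
    expect_true(all(diff(e) < 0))
    # affine: second differences vanish
    expect_equal(max(abs(diff(diff(e)))), 0, tolerance = 1e-9)
    expect_equal(suppressWarnings(gestational_egfr(2 * 55.25, gw)), 0,
                 tolerance = 1e-9)
  }
  expect_warning(gestational_egfr(115, 22), "non-physiologic")
  expect_error(gestational_egfr(40, 2), "pre-implantation")
  expect_error(gestational_egfr(-5, 22), "> 0")
})

test_that("the absolute normal GFR derives from the BSA de-indexing", {
  expect_equal(round(derive_normal_gfr(110.1, 1.62, 1.73), 1), 103.1)
  expect_equal(derive_normal_gfr(100, 1.73, 1.73), 100)
  expect_equal(derive_normal_gfr(100, 0.865, 1.73), 50)
  expect_error(derive_normal_gfr(100, -1), "> 0")
})

test_that("creatinine unit conversion uses the 88.42 molar factor", {
  expect_equal(mg_dl_to_umol_l(0), 0)
  expect_equal(mg_dl_to_umol_l(1), 88.42)
  x <- c(0.4, 0.62, 1.3)
  expect_equal(umol_l_to_mg_dl(mg_dl_to_umol_l(x)), x, tolerance = 1e-12)
  expect_error(mg_dl_to_umol_l(-1), ">= 0")
})

test_that("the canonical curve reproduces the published week-by-week medians", {
  tab <- ri_table_published()
  expect_equal(nrow(tab), 38L)
  expect_equal(tab$gw, 4:41)
  med <- round(predict(canonical_median_curve(), tab$gw), 1)
  expect_equal(med, tab$scr_median)
  # increments are computed from the rounded medians
  expect_equal(round(100 * (med / 55.25 - 1), 1), tab$scr_increment)
  expect_true(all(tab$scr_lower < tab$scr_median &
                  tab$scr_median < tab$scr_upper))
  expect_true(all(tab$egfr_lower < tab$egfr_median &
                  tab$egfr_median < tab$egfr_upper))
})

test_that("make_ri_table lays out rounded values and increments per week", {
  scr_curves <- list(
    `p2.5` = polynomial_curve(canonical_median_curve()$coefficients - c(10, 0, 0, 0, 0)),
    p50 = canonical_median_curve(),
    `p97.5` = polynomial_curve(canonical_median_curve()$coefficients + c(15, 0, 0, 0, 0)))
  tab <- make_ri_table(scr_curves)
  expect_equal(nrow(tab), 38L)
  expect_equal(tab$scr_median[tab$gw == 4], 54.3)
  expect_equal(tab$scr_increment[tab$gw == 4], -1.7)
  expect_equal(tab$scr_median[tab$gw == 41], 48.7)
  expect_equal(tab$scr_increment[tab$gw == 41], -11.9)
  expect_equal(tab$scr_upper - tab$scr_median, rep(15, 38))
  expect_false("egfr_median" %in% names(tab))
})

test_that("eGFR parameters round-trip through the YAML config", {
  p <- read_egfr_parameters()
  q <- egfr_parameters()
  expect_equal(p$bsc, q$bsc)
  expect_equal(p$normal_gfr, q$normal_gfr)
  expect_equal(p$median_curve$coefficients, q$median_curve$coefficients)
  expect_error(egfr_parameters(bsc = -1), "> 0")
  expect_error(egfr_parameters(median_curve = polynomial_curve(c(-5))),
               "positive")
})

test_that("eGFR reference intervals inherit the SCr pipeline structure", {
  pl <- default_pipeline()
  gw <- 4:41
  lo <- predict(pl$egfr$curves$p2.5, gw)
  med <- predict(pl$egfr$curves$p50, gw)
  hi <- predict(pl$egfr$curves$p97.5, gw)
  expect_true(all(lo < med & med < hi))
  # hyperfiltration peaks mid-pregnancy: median eGFR maximal near the SCr nadir
  peak <- gw[which.max(med)]
  expect_true(peak >= 18 && peak <= 28)
  expect_true(all(c("egfr_lower", "egfr_median", "egfr_upper",
                    "egfr_increment") %in% names(pl$ri_table)))
})

test_that("a near-noiseless cohort maps onto the analytic eGFR curve", {
  cfg <- cohort_config(n_subjects = 600, n_measurements = 900,
                       dispersion = 0.01, seed = 19L)
  cohort <- generate_cohort(cfg)
  res <- suppressWarnings(
    build_egfr_ri(cohort, resampling = resample_config(seed = 19, max_attempts = 50),
                  search = degree_search_config(repeats = 50, seed = 19),
                  require = "none"))
  gw <- 5:40
  analytic <- gestational_egfr(predict(canonical_median_curve(), gw), gw)
  expect_equal(predict(res$curves$p50, gw), analytic, tolerance = 0.05)
  width <- predict(res$curves$p97.5, gw) - predict(res$curves$p2.5, gw)
  # interval width is dominated by the within-period week-to-week trend
  expect_true(all(width < 25))
})
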