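# Mean-of-n bootstrap resampling of a gestational period, Gaussian
# acceptance criteria, order-statistic 95% interval, and coverage
# verification against the original measurements.

#' Configuration of the bootstrap resampling
#'
#' @param n_pick Number of values averaged per draw (default 2). Values
#'   within one draw are picked without replacement; draws are independent,
#'   so the procedure as a whole resamples with replacement.
#' @param t_iter Number of resampled means forming one candidate set
#'   (default 120, the CLSI-recommended observation count).
#' @param max_attempts Retry cap when a candidate set fails the acceptance
#'   criteria (default 1000).
#' @param seed Integer master seed; per-attempt sub-seeds are derived from
#'   it so the whole retry sequence is reproducible.
#' @return An object of class `resample_config`.
#' @export
resample_config <- function(n_pick = 2L, t_iter = 120L, max_attempts = 1000L,
                            seed = 1L) {
  if (n_pick < 2L) stop("`n_pick` must be >= 2")
  if (t_iter < 40L) stop("`t_iter` must be >= 40")
  if (max_attempts < 1L) stop("`max_attempts` must be >= 1")
  structure(list(n_pick = as.integer(n_pick), t_iter = as.integer(t_iter),
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "resample_config")
}

#' Gaussian acceptance criteria for a resample set
#'
#' A resample set is considered normally distributed when its Pearson
#' kurtosis is close to 3, its skewness close to 0, and the Shapiro-Wilk
#' test does not reject normality.
#'
#' @param kurtosis_range Acceptable Pearson kurtosis interval (normal = 3),
#'   default `c(2.5, 3.5)`.
#' @param skewness_range Acceptable skewness interval, default `c(-0.5, 0.5)`.
#' @param shapiro_p_min Minimum Shapiro-Wilk p-value, default 0.05.
#' @return An object of class `gaussian_criteria`.
#' @export
gaussian_criteria <- function(kurtosis_range = c(2.5, 3.5),
                              skewness_range = c(-0.5, 0.5),
                              shapiro_p_min = 0.05) {
  structure(list(kurtosis_range = kurtosis_range,
                 skewness_range = skewness_range,
                 shapiro_p_min = shapiro_p_min),
            class = "gaussian_criteria")
}

# t_iter means of n_pick values drawn (without replacement within a draw)
# from x, using the current RNG state. Vectorised for the n_pick = 2 case.
.resample_means <- function(x, n_pick, t_iter) {
  n <- length(x)
  if (n < n_pick) stop("insufficient data: fewer values than `n_pick`")
  if (n_pick == 2L) {
    i <- sample.int(n, t_iter, replace = TRUE)
    j <- sample.int(n - 1L, t_iter, replace = TRUE)
    j <- j + (j >= i)                    # j uniform on {1..n} \ {i}
    (x[i] + x[j]) / 2
  } else {
    vapply(seq_len(t_iter), function(k) mean(x[sample.int(n, n_pick)]),
           numeric(1))
  }
}

#' Resample a gestational period into a set of bootstrap means
#'
#' Each of the `t_iter` values is the arithmetic mean of `n_pick` SCr
#' measurements drawn at random from the period. Every resampled mean lies
#' within the range of the original data by construction.
#'
#' @param gp A `gestational_period` (see [bin_into_periods()]) or a plain
#'   numeric vector of measurements.
#' @param cfg A [resample_config()].
#' @return Numeric vector of `t_iter` resampled means (unsorted).
#' @export
resample_period <- function(gp, cfg = resample_config()) {
  x <- if (inherits(gp, "gestational_period")) gp$values else as.numeric(gp)
  set.seed(cfg$seed)
  .resample_means(x, cfg$n_pick, cfg$t_iter)
}

#' Test a sample against the Gaussian acceptance criteria
#'
#' Computes the standardised third moment (skewness), the Pearson kurtosis
#' (non-excess; normal = 3) and the Shapiro-Wilk p-value, and checks all
#' three against `criteria`.
#'
#' @param values Numeric vector, at least 3 values.
#' @param criteria A [gaussian_criteria()].
#' @return List with `kurtosis`, `skewness`, `shapiro_p`, logical `pass`,
#'   and `reason` (`NA` when passing, otherwise the first failed check).
#' @export
check_gaussian <- function(values, criteria = gaussian_criteria()) {
  if (length(values) < 3L) stop("need at least 3 values")
  if (sd(values) == 0) {
    return(list(kurtosis = NA_real_, skewness = NA_real_,
                shapiro_p = NA_real_, pass = FALSE, reason = "zero variance"))
  }
  kur <- e1071::kurtosis(values, type = 1) + 3  # Pearson convention
  ske <- e1071::skewness(values, type = 1)
  sw <- shapiro.test(values)$p.value
  reason <- if (kur < criteria$kurtosis_range[1] || kur > criteria$kurtosis_range[2]) {
    "kurtosis"
  } else if (ske < criteria$skewness_range[1] || ske > criteria$skewness_range[2]) {
    "skewness"
  } else if (sw < criteria$shapiro_p_min) {
    "shapiro"
  } else NA_character_
  list(kurtosis = kur, skewness = ske, shapiro_p = sw,
       pass = is.na(reason), reason = reason)
}

#' Order-statistic ranks of the 95% interval for a resample set of size t
#'
#' The lower limit is the `ceiling(0.025 t)`-th and the upper limit the
#' `t + 1 - ceiling(0.025 t)`-th smallest value; for t = 120 these are the
#' 3rd and 118th values.
#'
#' @param t_iter Resample-set size (>= 40).
#' @return Integer vector `c(lower, upper)` of one-based ranks.
#' @export
ci_ranks <- function(t_iter) {
  if (t_iter < 40L) stop("`t_iter` must be >= 40")
  # tiny slack guards against 0.025 * t landing just above an integer
  r <- as.integer(ceiling(2.5 * t_iter / 100 - 1e-9))
  c(lower = r, upper = as.integer(t_iter) + 1L - r)
}

#' 95% interval of a sorted resample set
#'
#' @param sorted_values Resampled means sorted in ascending order, of length
#'   `t_iter`.
#' @param t_iter Expected length (default: length of the input).
#' @return Numeric `c(lower, upper)` — the order statistics at [ci_ranks()].
#' @export
ci_from_resamples <- function(sorted_values, t_iter = length(sorted_values)) {
  if (length(sorted_values) != t_iter) {
    stop(sprintf("expected %d values, got %d", t_iter, length(sorted_values)))
  }
  if (is.unsorted(sorted_values)) stop("values must be sorted ascending")
  r <- ci_ranks(t_iter)
  c(lower = sorted_values[r["lower"]], upper = sorted_values[r["upper"]])
}

#' Coverage of the original measurements by a candidate interval
#'
#' CLSI-style verification: the fraction of the period's original
#' measurements inside the closed interval `[lower, upper]` must reach 95%.
#'
#' @param gp A `gestational_period` or numeric vector of measurements.
#' @param lower,upper Interval bounds, `lower < upper`.
#' @return List with `coverage` (fraction in `[lower, upper]`) and logical
#'   `pass` (`coverage >= 0.95`).
#' @export
verify_coverage <- function(gp, lower, upper) {
  x <- if (inherits(gp, "gestational_period")) gp$values else as.numeric(gp)
  if (length(x) == 0L) stop("empty gestational period")
  if (!(lower < upper)) stop("`lower` must be < `upper`")
  coverage <- mean(x >= lower & x <= upper)
  list(coverage = coverage, pass = coverage >= 0.95)
}

#' Build the verified reference interval of one gestational period
#'
#' Repeatedly resamples the period (fresh sub-seed per attempt) until a
#' resample set passes the Gaussian criteria *and* its 95% order-statistic
#' interval covers at least 95% of the original measurements, or
#' `max_attempts` is exhausted. When the cap is hit, the attempt that came
#' closest is returned — Gaussian-passing attempts preferred, then highest
#' coverage — with `accepted = FALSE` so the caller can decide.
#'
#' @param gp A `gestational_period` (or numeric vector, wrapped ad hoc).
#' @param cfg A [resample_config()].
#' @param criteria A [gaussian_criteria()].
#' @return An object of class `resample_set`: sorted `values`,
#'   `diagnostics` (kurtosis/skewness/shapiro_p), `ci_lower`, `ci_upper`,
#'   `coverage`, logical `gaussian_pass`, `coverage_pass`, `accepted`,
#'   `attempts_used`, and the originating `period`.
#' @export
build_period_ri <- function(gp, cfg = resample_config(),
                            criteria = gaussian_criteria()) {
  if (!inherits(gp, "gestational_period")) {
    x <- as.numeric(gp)
    gp <- structure(list(label = NA_integer_, gw_lo = NA_integer_,
                         gw_hi = NA_integer_, midpoint = NA_real_, values = x),
                    class = "gestational_period")
  }
  if (length(gp$values) < cfg$n_pick) {
    stop("insufficient data: gestational period smaller than `n_pick`")
  }
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max, cfg$max_attempts)

  best <- NULL
  best_score <- c(-1, -1)  # (gaussian_pass, coverage)
  for (a in seq_len(cfg$max_attempts)) {
    set.seed(sub_seeds[a])
    v <- sort(.resample_means(gp$values, cfg$n_pick, cfg$t_iter))
    diag <- check_gaussian(v, criteria)
    ci <- ci_from_resamples(v, cfg$t_iter)
    cov <- if (ci["lower"] < ci["upper"]) {
      verify_coverage(gp, ci["lower"], ci["upper"])
    } else {
      list(coverage = 0, pass = FALSE)  # degenerate interval is never valid
    }
    cand <- list(values = v, diagnostics = diag[c("kurtosis", "skewness", "shapiro_p")],
                 ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
                 coverage = cov$coverage,
                 gaussian_pass = diag$pass, coverage_pass = cov$pass,
                 accepted = diag$pass && cov$pass, attempts_used = a,
                 period = gp[c("label", "gw_lo", "gw_hi", "midpoint")])
    cand$period$n <- length(gp$values)
    score <- c(as.numeric(diag$pass), cov$coverage)
    if (score[1] > best_score[1] ||
        (score[1] == best_score[1] && score[2] > best_score[2])) {
      best <- cand
      best_score <- score
    }
    if (cand$accepted) break
  }
  best$attempts_used <- if (best$accepted) best$attempts_used else cfg$max_attempts
  structure(best, class = "resample_set")
}

#' Percentile of a resample set by the order-statistic rank rule
#'
#' Generalises the 3rd/118th rule used for the 95% interval: for a lower-tail
#' percentile p the rank is `ceiling(p/100 * t)`, for an upper-tail
#' percentile `t + 1 - ceiling((1 - p/100) * t)`.
#'
#' @param rs A `resample_set` from [build_period_ri()].
#' @param p Percentile in (0, 100).
#' @return The corresponding order statistic of the resampled means.
#' @export
resample_percentile <- function(rs, p) {
  t <- length(rs$values)
  r <- if (p <= 50) {
    ceiling(p * t / 100 - 1e-9)
  } else {
    t + 1L - ceiling((100 - p) * t / 100 - 1e-9)
  }
  rs$values[max(1L, min(t, r))]
}

#' @export
print.resample_set <- function(x, ...) {
  cat(sprintf("resample_set GP%s [GW %s-%s], n = %s\n",
              x$period$label, x$period$gw_lo, x$period$gw_hi, x$period$n))
  cat(sprintf("  95%% interval [%.1f, %.1f]  coverage %.3f (%s)\n",
              x$ci_lower, x$ci_upper, x$coverage,
              if (x$coverage_pass) "pass" else "fail"))
  cat(sprintf("  kurtosis %.2f  skewness %.2f  Shapiro-Wilk p %.3f (%s)\n",
              x$diagnostics$kurtosis, x$diagnostics$skewness,
              x$diagnostics$shapiro_p,
              if (x$gaussian_pass) "pass" else "fail"))
  cat(sprintf("  accepted: %s after %d attempt(s)\n",
              x$accepted, x$attempts_used))
  invisible(x)
}
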