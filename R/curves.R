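# Polynomial curves over gestational weeks, and cross-validated degree
# selection. Raw ascending powers are used as the basis so that fitted
# coefficients can be read directly as the published formula's denominator;
# conditioning is acceptable on the GW 4-41 domain and degrees <= 5.

#' Polynomial curve over a gestational-week domain
#'
#' @param coefficients Numeric vector of coefficients in ascending powers
#'   (`c0 + c1*gw + c2*gw^2 + ...`); the degree is `length(coefficients) - 1`.
#' @param domain Numeric `c(lo, hi)` interval on which the curve is meant to
#'   be evaluated (default GW 4-41).
#' @return An object of class `polynomial_curve`.
#' @examples
#' crv <- polynomial_curve(c(2, 1))  # 2 + gw
#' predict(crv, 5)
#' @export
polynomial_curve <- function(coefficients, domain = c(4, 41)) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || anyNA(coefficients)) {
    stop("`coefficients` must be a non-empty numeric vector")
  }
  structure(list(coefficients = coefficients,
                 degree = length(coefficients) - 1L,
                 domain = as.numeric(domain)),
            class = "polynomial_curve")
}

#' @param object A `polynomial_curve`.
#' @param gw Gestational weeks at which to evaluate.
#' @param strict If `TRUE`, error when `gw` falls outside the curve domain
#'   (default `FALSE`: polynomials extrapolate smoothly).
#' @param ... Unused.
#' @rdname polynomial_curve
#' @export
predict.polynomial_curve <- function(object, gw, strict = FALSE, ...) {
  if (strict && any(gw < object$domain[1] | gw > object$domain[2])) {
    stop(sprintf("gw outside curve domain [%g, %g]",
                 object$domain[1], object$domain[2]))
  }
  drop(outer(gw, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.polynomial_curve <- function(x, ...) {
  terms <- sprintf("%.6g*gw^%d", x$coefficients, 0:x$degree)
  cat("polynomial_curve (degree ", x$degree, ", domain [",
      x$domain[1], ", ", x$domain[2], "])\n  ",
      paste(terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Configuration for cross-validated polynomial degree selection
#'
#' @param degree_range Candidate degrees (default 1:5).
#' @param k_folds Number of cross-validation folds (default 3, one per
#'   trimester-sized block of points).
#' @param repeats Number of random re-partitions over which the winning
#'   degree is tallied (default 1000).
#' @param seed Integer seed for the fold partitions.
#' @return An object of class `degree_search_config`.
#' @export
degree_search_config <- function(degree_range = 1:5, k_folds = 3L,
                                 repeats = 1000L, seed = 1L) {
  if (k_folds < 2) stop("`k_folds` must be >= 2")
  if (any(degree_range < 1)) stop("degrees must be >= 1")
  structure(list(degree_range = as.integer(sort(degree_range)),
                 k_folds = as.integer(k_folds),
                 repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "degree_search_config")
}

# Least-squares polynomial coefficients on raw powers, QR-based fast path.
.polyfit <- function(x, y, degree) {
  .lm.fit(outer(x, 0:degree, `^`), y)$coefficients
}

# Single k-fold CV pass: test MSE per candidate degree, one shared random
# partition (fold sizes differ by at most 1). Assumes current RNG state.
.cv_pass <- function(x, y, degrees, k_folds) {
  n <- length(x)
  fold <- sample(rep_len(seq_len(k_folds), n))
  min_train <- n - max(tabulate(fold, k_folds))
  if (max(degrees) + 1L > min_train) {
    stop(sprintf("degree %d too high for %d-fold CV on %d points",
                 max(degrees), k_folds, n))
  }
  mse <- numeric(length(degrees))
  for (f in seq_len(k_folds)) {
    test <- fold == f
    for (j in seq_along(degrees)) {
      beta <- .polyfit(x[!test], y[!test], degrees[j])
      pred <- drop(outer(x[test], 0:degrees[j], `^`) %*% beta)
      mse[j] <- mse[j] + mean((y[test] - pred)^2)
    }
  }
  mse / k_folds
}

#' k-fold cross-validated mean squared error of a polynomial degree
#'
#' Randomly partitions the points into `k_folds` folds (sizes differing by
#' at most one), fits an ordinary least-squares polynomial of the requested
#' degree on k-1 folds, and averages the held-out mean squared error over
#' folds.
#'
#' @param x,y Coordinates of the points (e.g. GP midpoints and percentile
#'   values).
#' @param degree Polynomial degree to score.
#' @param k_folds Number of folds (default 3).
#' @param seed Optional integer seed; with the same seed two calls return
#'   identical MSE.
#' @return The cross-validated MSE (numeric scalar).
#' @export
cv_mse <- function(x, y, degree, k_folds = 3L, seed = NULL) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < k_folds) stop("need at least `k_folds` points")
  if (!is.null(seed)) set.seed(seed)
  .cv_pass(x, y, degree, k_folds)
}

#' Select a polynomial degree by repeated cross-validation with modal voting
#'
#' For each of `cfg$repeats` random fold partitions, every candidate degree
#' is scored by k-fold cross-validation and the degree with the smallest MSE
#' wins the repeat; the degree winning most repeats is selected. Ties (in a
#' single repeat or in the final tally) break toward the smaller degree.
#'
#' @param x,y Coordinates of the points.
#' @param cfg A [degree_search_config()].
#' @return A list with elements `degree` (the modal optimal degree),
#'   `frequency` (named integer vector over candidate degrees, summing to
#'   `cfg$repeats`) and `config`.
#' @export
select_degree <- function(x, y, cfg = degree_search_config()) {
  set.seed(cfg$seed)
  degrees <- cfg$degree_range
  wins <- integer(length(degrees))
  # degrees whose MSE ties the minimum up to numerical noise (exact fits)
  # count as ties; the first (smallest) degree wins the repeat
  tie_tol <- 1e-9 * (mean(y^2) + 1)
  for (r in seq_len(cfg$repeats)) {
    mse <- .cv_pass(x, y, degrees, cfg$k_folds)
    pick <- which(mse - min(mse) <= tie_tol)[1]
    wins[pick] <- wins[pick] + 1L
  }
  names(wins) <- degrees
  list(degree = degrees[which.max(wins)], frequency = wins, config = cfg)
}

#' Fit a polynomial of fixed degree by ordinary least squares
#'
#' @param x,y Coordinates of the points; needs `length(x) >= degree + 1`.
#' @param degree Polynomial degree.
#' @param domain Domain recorded on the returned curve (default the x-range).
#' @return A [polynomial_curve()]. When `length(x) == degree + 1` with
#'   distinct `x` the fit interpolates the points exactly.
#' @export
fit_polynomial <- function(x, y, degree, domain = range(x)) {
  if (length(x) < degree + 1L) stop("need at least degree + 1 points")
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  beta <- unname(coef(fit))
  if (anyNA(beta)) stop("rank-deficient design (duplicate x values?)")
  polynomial_curve(beta, domain = domain)
}

#' Smooth gestational-period percentiles into week-level curves
#'
#' Takes the per-GP resample sets of [build_period_ri()], extracts the
#' requested percentile of each accepted resample set, and fits one
#' polynomial curve per percentile: the degree is chosen with
#' [select_degree()] and the final fit uses all points. The pre-implantation
#' period (any GP overlapping GW 0-3) is excluded, and returned curves are
#' defined on GW 4-41 so every individual week gets an exact limit.
#'
#' @param period_ris List of `resample_set` objects (one per GP).
#' @param percentiles Percentiles to smooth, default `c(2.5, 50, 97.5)`.
#' @param cfg A [degree_search_config()].
#' @param require Acceptance level demanded of every contributing GP:
#'   `"gaussian"` (default) requires the Gaussian distribution criteria,
#'   which gate the construction of the percentile limits; `"full"`
#'   additionally requires the coverage confirmation; `"none"` uses all GPs.
#'   With `"gaussian"`, GPs failing only coverage are kept with a warning.
#' @param domain Domain of the returned curves, default `c(4, 41)`.
#' @return Named list of [polynomial_curve()] objects (`"p2.5"`, `"p50"`,
#'   ...), with the degree-selection `frequency` tables attached as
#'   attribute `"degree_search"`.
#' @export
smooth_limits <- function(period_ris, percentiles = c(2.5, 50, 97.5),
                          cfg = degree_search_config(),
                          require = c("gaussian", "full", "none"),
                          domain = c(4, 41)) {
  require <- match.arg(require)
  keep <- vapply(period_ris, function(rs) rs$period$gw_lo >= 4, logical(1))
  ris <- period_ris[keep]
  if (length(ris) < 6L) stop("need at least 6 gestational periods beyond the pre-implantation period")
  lab <- vapply(ris, function(rs) sprintf("GP%d [%d-%d]", rs$period$label,
                                          rs$period$gw_lo, rs$period$gw_hi), character(1))
  if (require != "none") {
    bad_g <- !vapply(ris, function(rs) rs$gaussian_pass, logical(1))
    if (any(bad_g)) {
      stop("resample sets failing the Gaussian criteria: ",
           paste(lab[bad_g], collapse = ", "))
    }
    bad_c <- !vapply(ris, function(rs) rs$coverage_pass, logical(1))
    if (any(bad_c)) {
      msg <- paste("coverage confirmation (>= 95% of original data inside the",
                   "resampled 95% interval) failed for:",
                   paste(lab[bad_c], collapse = ", "))
      if (require == "full") stop(msg) else warning(msg)
    }
  }
  x <- vapply(ris, function(rs) rs$period$midpoint, numeric(1))
  out <- list()
  searches <- list()
  for (p in percentiles) {
    y <- vapply(ris, function(rs) resample_percentile(rs, p), numeric(1))
    sel <- select_degree(x, y, cfg)
    out[[paste0("p", format(p))]] <- fit_polynomial(x, y, sel$degree, domain = domain)
    searches[[paste0("p", format(p))]] <- sel$frequency
  }
  attr(out, "degree_search") <- searches
  out
}
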