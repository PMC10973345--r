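# Synthetic SCr-by-GW cohort generator.
#
# Per-GW distribution is a shifted (3-parameter) log-normal:
#   SCr = shift + (median - shift) * exp(sigma * Z),   Z ~ N(0,1)
# so the median is exactly the truth curve, the skewness is controlled by
# sigma alone, and the shift absorbs the difference between the requested
# coefficient of variation and the one sigma would imply. Quantiles are
# closed-form, which gives downstream recovery tests an exact oracle.

#' Configuration for a synthetic gestational SCr cohort
#'
#' Describes a cohort of healthy-pregnancy serum creatinine measurements:
#' how many subjects and measurements, how sampling concentrates across
#' gestation, and the per-week SCr distribution (median trajectory,
#' coefficient of variation, right-skew).
#'
#' @param n_subjects Number of distinct subjects (default 957).
#' @param n_measurements Total number of measurements, `>= n_subjects`; each
#'   subject contributes at most one measurement per gestational week
#'   (default 1484).
#' @param gw_range Integer vector `c(lo, hi)` within `[0, 41]`.
#' @param sampling_weights Per-GW probability of a measurement falling in
#'   that week, over `gw_range`; must sum to 1. Default:
#'   [default_sampling_weights()], strongly third-trimester weighted.
#' @param truth_median_curve A [polynomial_curve()] giving the median SCr
#'   (umol/L) for GW >= 4. Default: the canonical degree-4 curve of
#'   [canonical_median_curve()].
#' @param baseline_scr Constant median SCr for the pre-implantation weeks
#'   GW 0-3 (umol/L), default 55.25.
#' @param dispersion Coefficient of variation of SCr around the per-week
#'   median; must satisfy `dispersion < sqrt(exp(sigma^2) - 1)` where sigma
#'   is implied by `skew` (the shift must stay non-negative). Default 0.12.
#' @param skew Population skewness of the per-week distribution, `> 0`
#'   (right-skewed). Default 0.8, below the 1.5 regime in which the
#'   mean-of-two bootstrap behaves well.
#' @param seed Integer seed making the cohort reproducible.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [true_quantile()]
#' @export
cohort_config <- function(n_subjects = 957,
                          n_measurements = 1484,
                          gw_range = c(0L, 41L),
                          sampling_weights = NULL,
                          truth_median_curve = canonical_median_curve(),
                          baseline_scr = 55.25,
                          dispersion = 0.12,
                          skew = 0.8,
                          seed = 1L) {
  gw_range <- as.integer(gw_range)
  if (length(gw_range) != 2L || anyNA(gw_range) ||
      gw_range[1] < 0L || gw_range[2] > 41L || gw_range[1] > gw_range[2]) {
    stop("invalid config: `gw_range` must be an integer interval within [0, 41]")
  }
  if (is.null(sampling_weights)) {
    sampling_weights <- default_sampling_weights(gw_range)
  }
  gws <- seq.int(gw_range[1], gw_range[2])
  if (length(sampling_weights) != length(gws) || any(sampling_weights < 0)) {
    stop("invalid config: `sampling_weights` needs one non-negative weight per GW in `gw_range`")
  }
  if (abs(sum(sampling_weights) - 1) > 1e-8) {
    stop("invalid config: `sampling_weights` must sum to 1")
  }
  if (n_measurements < n_subjects) {
    stop("invalid config: `n_measurements` must be >= `n_subjects`")
  }
  if (n_measurements > n_subjects * length(gws)) {
    stop("invalid config: more measurements than distinct (subject, GW) slots")
  }
  if (dispersion < 0) stop("invalid config: `dispersion` must be >= 0")
  if (skew <= 0) stop("invalid config: `skew` must be > 0")
  if (baseline_scr <= 0) stop("invalid config: `baseline_scr` must be > 0")
  sigma <- .sdlog_from_skew(skew)
  cv_max <- sqrt(exp(sigma^2) - 1)
  if (dispersion >= cv_max) {
    stop(sprintf(
      "invalid config: `dispersion` = %.3f incompatible with `skew` = %.2f (must be < %.3f)",
      dispersion, skew, cv_max))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_measurements = as.integer(n_measurements),
         gw_range = gw_range,
         sampling_weights = sampling_weights / sum(sampling_weights),
         truth_median_curve = truth_median_curve,
         baseline_scr = baseline_scr,
         dispersion = dispersion,
         skew = skew,
         sigma = sigma,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Default third-trimester-weighted sampling probabilities
#'
#' Prenatal SCr testing concentrates late in pregnancy: roughly 10% of
#' measurements fall in GW 0-13, 20% in GW 14-27 and 70% in GW 28-41,
#' uniformly within each block. Weights are renormalised over `gw_range`.
#'
#' @param gw_range Integer interval `c(lo, hi)` within `[0, 41]`.
#' @return Numeric vector of probabilities, one per GW, summing to 1.
#' @export
default_sampling_weights <- function(gw_range = c(0L, 41L)) {
  gws <- seq.int(gw_range[1], gw_range[2])
  block_mass <- c(0.10, 0.20, 0.70) / 14  # per-week mass within each block
  w <- ifelse(gws <= 13, block_mass[1], ifelse(gws <= 27, block_mass[2], block_mass[3]))
  w / sum(w)
}

# Invert gamma = (w + 2) * sqrt(w - 1), w = exp(sigma^2), for the log-normal
# sigma giving population skewness `gamma`. Substituting u = sqrt(w - 1)
# yields the depressed cubic u^3 + 3u - gamma = 0, solved by Cardano.
.sdlog_from_skew <- function(skew) {
  d <- sqrt(skew^2 / 4 + 1)
  u <- (skew / 2 + d)^(1 / 3) - (d - skew / 2)^(1 / 3)
  sqrt(log1p(u^2))
}

# Shift of the 3-parameter log-normal reproducing CV `cv` at median `m`:
# mean = c + (m - c) A, sd = (m - c) B with A = exp(s^2/2), B = A sqrt(e^{s^2}-1).
.lognormal_shift <- function(m, cv, sigma) {
  if (cv == 0) return(m)
  a <- exp(sigma^2 / 2)
  b <- a * sqrt(expm1(sigma^2))
  m * (b - cv * a) / (cv * (1 - a) + b)
}

#' Median SCr implied by a cohort configuration at one gestational week
#'
#' The truth curve for GW >= 4, the constant pre-implantation baseline for
#' GW 0-3.
#'
#' @param config A [cohort_config()].
#' @param gw Integer gestational week(s).
#' @return Median SCr in umol/L.
#' @export
truth_median <- function(config, gw) {
  ifelse(gw < 4, config$baseline_scr,
         predict(config$truth_median_curve, gw))
}

#' Exact quantile of the generator's per-GW SCr distribution
#'
#' Closed-form quantile of the shifted log-normal used by
#' [generate_cohort()]; serves as the independent oracle for recovery tests.
#'
#' @param config A [cohort_config()].
#' @param gw Integer gestational week.
#' @param p Probability in (0, 1).
#' @return SCr value in umol/L; monotone increasing in `p`.
#' @export
true_quantile <- function(config, gw, p) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly in (0, 1)")
  m <- truth_median(config, gw)
  shift <- .lognormal_shift(m, config$dispersion, config$sigma)
  shift + (m - shift) * exp(config$sigma * qnorm(p))
}

#' Generate a synthetic cohort of SCr measurements
#'
#' Draws `n_measurements` SCr values across `n_subjects` subjects. Every
#' subject contributes at least one measurement; extra measurements are
#' spread randomly, and within a subject all gestational weeks are distinct
#' (repeat visits land in different weeks). SCr is drawn from the shifted
#' log-normal around the configured median trajectory.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with columns `subject_id` (character), `gw`
#'   (integer) and `scr` (umol/L), one row per measurement, ordered by
#'   subject then week. Reproducible given `config$seed`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 50, n_measurements = 80))
#' range(cohort$gw)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  gws <- seq.int(config$gw_range[1], config$gw_range[2])
  n_gw <- length(gws)

  # measurements per subject: everyone gets 1, extras go to random subjects
  k <- rep(1L, config$n_subjects)
  extra <- config$n_measurements - config$n_subjects
  if (extra > 0) {
    add <- tabulate(sample.int(config$n_subjects, extra, replace = TRUE),
                    nbins = config$n_subjects)
    k <- k + add
    while (any(k > n_gw)) {     # redistribute overflow beyond one-per-week
      over <- sum(k - pmin(k, n_gw))
      k <- pmin(k, n_gw)
      room <- which(k < n_gw)
      add <- tabulate(room[sample.int(length(room), over, replace = TRUE,
                                      prob = (n_gw - k[room]))],
                      nbins = config$n_subjects)
      k <- k + add
    }
  }

  subject_id <- rep(sprintf("S%04d", seq_len(config$n_subjects)), times = k)
  gw <- unlist(lapply(k, function(ki) {
    gws[sample.int(n_gw, ki, replace = FALSE, prob = config$sampling_weights)]
  }), use.names = FALSE)

  m <- truth_median(config, gw)
  shift <- .lognormal_shift(m, config$dispersion, config$sigma)
  scr <- shift + (m - shift) * exp(config$sigma * rnorm(length(gw)))

  out <- data.frame(subject_id = subject_id, gw = as.integer(gw), scr = scr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$gw), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a cohort CSV
#'
#' The on-disk format has header `subject_id,gw,scr_umol_l`.
#'
#' @param cohort Data frame as returned by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the cohort data frame with columns
#'   `subject_id`, `gw`, `scr`; `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(subject_id = cohort$subject_id, gw = cohort$gw,
                    scr_umol_l = cohort$scr)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "gw", "scr_umol_l")
  if (!all(need %in% names(raw))) {
    stop("cohort CSV must have columns subject_id, gw, scr_umol_l")
  }
  data.frame(subject_id = as.character(raw$subject_id),
             gw = as.integer(raw$gw), scr = as.numeric(raw$scr_umol_l),
             stringsAsFactors = FALSE)
}
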