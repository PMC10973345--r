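# The gestational eGFR formula: renal hyperfiltration quantities, the
# week-specific correction factor k_gw, and the published canonical
# parameter set
#
#   eGFR(SCr, GW) = (2 - SCr/55.25) * 103.1 * 55.25 /
#                   (56.7 - 0.223 GW - 0.113 GW^2 + 0.00545 GW^3 - 0.0000653 GW^4)
#
# with SCr in umol/L and eGFR in absolute mL/min (not BSA-indexed).

.CANONICAL_MEDIAN_COEF <- c(56.7, -0.223, -0.113, 0.00545, -0.0000653)
.MG_DL_TO_UMOL_L <- 88.42  # creatinine molar mass convention

#' Canonical gestational median SCr curve
#'
#' The degree-4 polynomial (ascending powers of GW, domain GW 4-41) giving
#' the median SCr trajectory of normal pregnancy, with its mid-pregnancy
#' nadir near GW 22-23.
#'
#' @return A [polynomial_curve()].
#' @export
canonical_median_curve <- function() {
  polynomial_curve(.CANONICAL_MEDIAN_COEF, domain = c(4, 41))
}

#' Parameters of the gestational eGFR formula
#'
#' @param bsc Baseline serum creatinine: the pre-implantation (GW 0-3)
#'   median SCr in umol/L (canonical 55.25).
#' @param normal_gfr Absolute normal GFR of non-pregnant women in mL/min
#'   (canonical 103.1 = 110.1 mL/min/1.73 m2 de-indexed to a 1.62 m2 body
#'   surface area, see [derive_normal_gfr()]).
#' @param median_curve [polynomial_curve()] of the gestational median SCr
#'   (canonical: [canonical_median_curve()]).
#' @return An object of class `egfr_parameters`.
#' @export
egfr_parameters <- function(bsc = 55.25, normal_gfr = 103.1,
                            median_curve = canonical_median_curve()) {
  if (bsc <= 0 || normal_gfr <= 0) stop("`bsc` and `normal_gfr` must be > 0")
  gws <- seq(median_curve$domain[1], median_curve$domain[2])
  if (any(predict(median_curve, gws) <= 0)) {
    stop("`median_curve` must be positive on its domain")
  }
  structure(list(bsc = bsc, normal_gfr = normal_gfr,
                 median_curve = median_curve),
            class = "egfr_parameters")
}

#' Read eGFR parameters from a YAML config
#'
#' The shipped canonical set lives at
#' `system.file("extdata", "canonical_params.yaml", package = "gestgfr")`.
#'
#' @param path Path to a YAML file with fields `bsc`, `normal_gfr`,
#'   `median_curve` (list with `coefficients`, `domain`).
#' @return An [egfr_parameters()] object.
#' @export
read_egfr_parameters <- function(path = system.file("extdata", "canonical_params.yaml",
                                                    package = "gestgfr")) {
  y <- yaml::read_yaml(path)
  egfr_parameters(bsc = y$bsc, normal_gfr = y$normal_gfr,
                  median_curve = polynomial_curve(y$median_curve$coefficients,
                                                  domain = unlist(y$median_curve$domain)))
}

#' Hyperfiltration gap
#'
#' Difference between the pre-implantation baseline SCr and the measured
#' SCr; positive values indicate hyperfiltration (SCr pushed below
#' baseline by the raised GFR).
#'
#' @param bsc Baseline SCr, umol/L (> 0).
#' @param scr Measured SCr, umol/L (> 0).
#' @return `bsc - scr` in umol/L.
#' @export
hyperfiltration_gap <- function(bsc, scr) {
  if (any(bsc <= 0) || any(scr <= 0)) stop("`bsc` and `scr` must be > 0")
  bsc - scr
}

#' Simple hyperfiltration gap ratio
#'
#' The hyperfiltration gap as a fraction of baseline: `(bsc - scr) / bsc`.
#'
#' @inheritParams hyperfiltration_gap
#' @return Dimensionless ratio.
#' @export
simple_hyperfiltration_gap_ratio <- function(bsc, scr) {
  hyperfiltration_gap(bsc, scr) / bsc
}

#' Overall hyperfiltration ratio
#'
#' One plus the simple gap ratio, i.e. `2 - scr/bsc`: the multiplicative
#' change in filtration relative to the non-pregnant state (1 at baseline,
#' 0 when SCr reaches twice the baseline).
#'
#' @inheritParams hyperfiltration_gap
#' @return Dimensionless ratio.
#' @export
overall_hyperfiltration_ratio <- function(bsc, scr) {
  1 + simple_hyperfiltration_gap_ratio(bsc, scr)
}

#' Week-specific correction factor k_gw
#'
#' Ratio of the baseline SCr to the gestational median SCr at week `gw`,
#' `bsc / median_curve(gw)`: it rescales the hyperfiltration-derived eGFR
#' for the curvilinear median trajectory, peaking at the mid-pregnancy SCr
#' nadir.
#'
#' @param gw Gestational week(s) within the median curve domain (GW 0-3 is
#'   the pre-implantation period and is rejected).
#' @param params An [egfr_parameters()].
#' @return Dimensionless factor (1 where the median equals baseline).
#' @export
k_gw <- function(gw, params = egfr_parameters()) {
  if (any(gw < 4)) {
    stop("pre-implantation period (GW 0-3): no hemodynamic change is assumed, k_gw undefined")
  }
  params$bsc / predict(params$median_curve, gw, strict = TRUE)
}

#' Gestational eGFR from a serum creatinine measurement
#'
#' The hyperfiltration eGFR formula: overall hyperfiltration ratio times
#' the absolute normal GFR times [k_gw()]. Affine and strictly decreasing
#' in SCr at fixed week; equals `normal_gfr * k_gw(gw)` at `scr = bsc` and
#' reaches 0 at `scr = 2 * bsc` (values at or beyond that point are
#' non-physiologic and trigger a warning).
#'
#' @param scr Measured SCr, umol/L (> 0).
#' @param gw Gestational week(s), 4-41.
#' @param params An [egfr_parameters()].
#' @return eGFR in mL/min (absolute, not BSA-indexed).
#' @examples
#' gestational_egfr(40, 20)  # ~181 mL/min
#' @export
gestational_egfr <- function(scr, gw, params = egfr_parameters()) {
  if (any(scr <= 0)) stop("`scr` must be > 0")
  if (any(scr >= 2 * params$bsc)) {
    warning("SCr >= 2 * baseline: non-physiologic for the hyperfiltration model (eGFR <= 0)")
  }
  overall_hyperfiltration_ratio(params$bsc, scr) * params$normal_gfr * k_gw(gw, params)
}

#' De-index a BSA-indexed GFR to an absolute GFR
#'
#' Converts a population GFR given per 1.73 m2 of body surface area to an
#' absolute value for a given BSA: `gfr_indexed * bsa / bsa_ref`.
#'
#' @param gfr_indexed GFR in mL/min/1.73 m2.
#' @param bsa Body surface area, m2.
#' @param bsa_ref Reference BSA, m2 (default 1.73).
#' @return Absolute GFR in mL/min.
#' @examples
#' derive_normal_gfr(110.1, 1.62)  # 103.1 mL/min
#' @export
derive_normal_gfr <- function(gfr_indexed, bsa, bsa_ref = 1.73) {
  if (any(c(gfr_indexed, bsa, bsa_ref) <= 0)) stop("all inputs must be > 0")
  gfr_indexed * bsa / bsa_ref
}

#' Creatinine unit conversions
#'
#' Converts serum creatinine between mg/dL and umol/L using the molar-mass
#' factor 88.42.
#'
#' @param scr_mg_dl,scr_umol_l Non-negative SCr value(s).
#' @return Converted value(s).
#' @export
mg_dl_to_umol_l <- function(scr_mg_dl) {
  if (any(scr_mg_dl < 0)) stop("SCr must be >= 0")
  scr_mg_dl * .MG_DL_TO_UMOL_L
}

#' @rdname mg_dl_to_umol_l
#' @export
umol_l_to_mg_dl <- function(scr_umol_l) {
  if (any(scr_umol_l < 0)) stop("SCr must be >= 0")
  scr_umol_l / .MG_DL_TO_UMOL_L
}

#' Build GW-specific eGFR reference intervals
#'
#' Transforms each SCr measurement at GW >= 4 with [gestational_egfr()],
#' then reuses the whole reference-interval machinery — binning, bootstrap
#' resampling with Gaussian acceptance, coverage verification, and
#' cross-validated polynomial smoothing — on the eGFR scale.
#'
#' @param measurements Cohort data frame (`gw`, `scr`).
#' @param params An [egfr_parameters()].
#' @param binning A [binning_config()].
#' @param resampling A [resample_config()]; per-period sub-seeds derive
#'   from its seed.
#' @param search A [degree_search_config()].
#' @param criteria A [gaussian_criteria()].
#' @param require Acceptance level passed to [smooth_limits()].
#' @return List with `periods`, `period_ris` and `curves` (percentile ->
#'   [polynomial_curve()], mL/min scale).
#' @export
build_egfr_ri <- function(measurements, params = egfr_parameters(),
                          binning = binning_config(),
                          resampling = resample_config(),
                          search = degree_search_config(),
                          criteria = gaussian_criteria(),
                          require = "gaussian") {
  keep <- measurements$gw >= 4
  if (!any(keep)) stop("no measurements at GW >= 4")
  egfr <- gestational_egfr(measurements$scr[keep], measurements$gw[keep], params)
  transformed <- data.frame(gw = measurements$gw[keep], scr = egfr)
  periods <- bin_into_periods(transformed, binning)
  ris <- build_period_ris(periods, resampling, criteria)
  curves <- smooth_limits(ris, percentiles = c(2.5, 50, 97.5), cfg = search,
                          require = require)
  list(periods = periods, period_ris = ris, curves = curves)
}

#' Combined SCr / eGFR reference-interval table by gestational week
#'
#' Evaluates the smoothed percentile curves at every integer week GW 4-41
#' and reports, per analyte, the lower limit (2.5th), upper limit (97.5th)
#' and median together with the increment relative to the pre-implantation
#' baseline. Values are rounded to 0.1 and increments are computed from the
#' rounded values (the convention that reproduces the published table).
#'
#' @param scr_curves Named list of SCr curves (`p2.5`, `p50`, `p97.5`), as
#'   from [smooth_limits()].
#' @param egfr_curves Same, on the eGFR scale; may be `NULL` to omit eGFR
#'   columns.
#' @param params An [egfr_parameters()]; its `bsc` is the SCr increment
#'   baseline.
#' @param egfr_baseline Baseline for the eGFR increment column, mL/min.
#'   Default: the fitted median eGFR curve extrapolated to the midpoint of
#'   the pre-implantation period (GW 1.5).
#' @return Data frame with one row per GW 4-41: `gw`, `scr_lower`,
#'   `scr_upper`, `scr_median`, `scr_increment` (%), and the four eGFR
#'   analogues when `egfr_curves` is given.
#' @export
make_ri_table <- function(scr_curves, egfr_curves = NULL,
                          params = egfr_parameters(), egfr_baseline = NULL) {
  gw <- 4:41
  r1 <- function(v) round(v, 1)
  scr_median <- r1(predict(scr_curves$p50, gw))
  out <- data.frame(
    gw = gw,
    scr_lower = r1(predict(scr_curves$p2.5, gw)),
    scr_upper = r1(predict(scr_curves$p97.5, gw)),
    scr_median = scr_median,
    scr_increment = r1(100 * (scr_median / params$bsc - 1)))
  if (!is.null(egfr_curves)) {
    if (is.null(egfr_baseline)) {
      egfr_baseline <- predict(egfr_curves$p50, 1.5)
    }
    egfr_median <- r1(predict(egfr_curves$p50, gw))
    out$egfr_lower <- r1(predict(egfr_curves$p2.5, gw))
    out$egfr_upper <- r1(predict(egfr_curves$p97.5, gw))
    out$egfr_median <- egfr_median
    out$egfr_increment <- r1(100 * (egfr_median / r1(egfr_baseline) - 1))
  }
  out
}

#' The published gestational SCr / eGFR reference-interval table
#'
#' Reads the reference-interval table shipped with the package (transcribed
#' from the published week-by-week table): per GW 4-41 the SCr and eGFR
#' 2.5th/97.5th percentile limits, medians, and increments (%) relative to
#' the pre-implantation period.
#'
#' @return Data frame with columns `gw`, `scr_lower`, `scr_upper`,
#'   `scr_median`, `scr_increment`, `egfr_lower`, `egfr_upper`,
#'   `egfr_median`, `egfr_increment`.
#' @export
ri_table_published <- function() {
  path <- system.file("extdata", "table1_gestational_ri.csv", package = "gestgfr")
  read.csv(path)
}
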