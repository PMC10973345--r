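# End-to-end orchestration and clinical result flagging.

#' Build reference intervals for every gestational period
#'
#' Runs [build_period_ri()] on each period with a per-period sub-seed
#' derived deterministically from `cfg$seed`, so the whole set is
#' reproducible under one master seed.
#'
#' @param periods A `gestational_periods` list from [bin_into_periods()].
#' @param cfg A [resample_config()].
#' @param criteria A [gaussian_criteria()].
#' @return List of `resample_set` objects, one per period.
#' @export
build_period_ris <- function(periods, cfg = resample_config(),
                             criteria = gaussian_criteria()) {
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, length(periods))
  lapply(seq_along(periods), function(g) {
    cfg_g <- cfg
    cfg_g$seed <- seeds[g]
    build_period_ri(periods[[g]], cfg_g, criteria)
  })
}

#' Analytic median SCr table from the canonical parameters
#'
#' Formula-only mode: evaluates the canonical median curve at every week
#' GW 4-41 with the increment relative to baseline, without any cohort.
#'
#' @param params An [egfr_parameters()].
#' @return Data frame with `gw`, `scr_median` (0.1 umol/L) and
#'   `scr_increment` (%, from the rounded median).
#' @export
median_scr_table <- function(params = egfr_parameters()) {
  gw <- seq(params$median_curve$domain[1], params$median_curve$domain[2])
  med <- round(predict(params$median_curve, gw), 1)
  data.frame(gw = gw, scr_median = med,
             scr_increment = round(100 * (med / params$bsc - 1), 1))
}

#' Run the full reference-interval and eGFR pipeline
#'
#' Generates (or accepts) a cohort, bins it into gestational periods,
#' builds the bootstrap SCr reference intervals, smooths them into
#' week-level curves, repeats the procedure on the eGFR scale, assembles
#' the combined week-by-week table, and compares the SCr percentile curves
#' against the packaged external reference. All randomness derives from one
#' master seed.
#'
#' @param cohort Optional cohort data frame (`gw`, `scr`); when `NULL` a
#'   synthetic cohort is generated from `config`.
#' @param config A [cohort_config()] used when `cohort` is `NULL`.
#' @param params An [egfr_parameters()].
#' @param binning A [binning_config()].
#' @param resampling A [resample_config()]; its seed is overridden by
#'   `seed`.
#' @param search A [degree_search_config()]; its seed is overridden by
#'   `seed`.
#' @param seed Master seed for the whole run.
#' @param require Acceptance level demanded by [smooth_limits()] of every
#'   gestational period (`"gaussian"`, `"full"` or `"none"`).
#' @param compare If `TRUE` (default), compare the smoothed SCr percentile
#'   curves (95/75/50) against the packaged external reference table.
#' @param out_dir Optional directory: when given, writes `cohort.csv`,
#'   `ri_table.csv`, `comparison.csv` and `diagnostics.csv` there.
#' @return List of class `gestgfr_pipeline` with elements `cohort`,
#'   `periods`, `scr_ris`, `scr_curves`, `egfr`, `ri_table`, `comparison`,
#'   `diagnostics` and `seed`.
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         params = egfr_parameters(),
                         binning = binning_config(),
                         resampling = resample_config(),
                         search = degree_search_config(),
                         seed = 1L, require = "gaussian", compare = TRUE,
                         out_dir = NULL) {
  seed <- as.integer(seed)
  if (is.null(cohort)) {
    config$seed <- seed
    cohort <- generate_cohort(config)
  }
  resampling$seed <- seed
  search$seed <- seed

  periods <- bin_into_periods(cohort, binning)
  scr_ris <- build_period_ris(periods, resampling, gaussian_criteria())
  scr_curves <- smooth_limits(scr_ris, percentiles = c(2.5, 50, 75, 95, 97.5),
                              cfg = search, require = require)

  egfr_resampling <- resampling
  egfr_resampling$seed <- seed + 1L
  egfr_search <- search
  egfr_search$seed <- seed + 1L
  egfr <- build_egfr_ri(cohort, params, binning, egfr_resampling, egfr_search,
                        require = require)

  ri_table <- make_ri_table(scr_curves, egfr$curves, params)

  comparison <- NULL
  if (compare) {
    comparison <- compare_to_reference(harel_reference(), scr_curves)
  }

  diagnostics <- do.call(rbind, lapply(c(scr_ris, egfr$period_ris), function(rs) {
    data.frame(analyte = NA_character_, label = rs$period$label,
               gw_lo = rs$period$gw_lo, gw_hi = rs$period$gw_hi,
               n = rs$period$n, kurtosis = rs$diagnostics$kurtosis,
               skewness = rs$diagnostics$skewness,
               shapiro_p = rs$diagnostics$shapiro_p,
               ci_lower = rs$ci_lower, ci_upper = rs$ci_upper,
               coverage = rs$coverage, gaussian_pass = rs$gaussian_pass,
               coverage_pass = rs$coverage_pass, accepted = rs$accepted,
               attempts_used = rs$attempts_used)
  }))
  diagnostics$analyte <- rep(c("scr", "egfr"),
                             c(length(scr_ris), length(egfr$period_ris)))

  result <- structure(
    list(cohort = cohort, periods = periods, scr_ris = scr_ris,
         scr_curves = scr_curves, egfr = egfr, ri_table = ri_table,
         comparison = comparison, diagnostics = diagnostics, seed = seed),
    class = "gestgfr_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write.csv(ri_table, file.path(out_dir, "ri_table.csv"), row.names = FALSE)
    write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"), row.names = FALSE)
    if (!is.null(comparison)) {
      write.csv(comparison$table, file.path(out_dir, "comparison.csv"),
                row.names = FALSE)
    }
  }
  result
}

#' @export
print.gestgfr_pipeline <- function(x, ...) {
  cat("gestgfr pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  cohort: ", nrow(x$cohort), " measurements, ",
      length(unique(x$cohort$subject_id)), " subjects\n", sep = "")
  cat("  gestational periods: ", length(x$periods), "\n", sep = "")
  acc <- sum(x$diagnostics$accepted[x$diagnostics$analyte == "scr"])
  cat("  SCr periods fully accepted (Gaussian + coverage): ", acc, "/",
      length(x$scr_ris), "\n", sep = "")
  cat("  RI table: GW ", min(x$ri_table$gw), "-", max(x$ri_table$gw), "\n", sep = "")
  invisible(x)
}

.flag_against <- function(value, lower, upper) {
  if (value < lower) "below" else if (value > upper) "above" else "within"
}

#' Flag a patient's SCr and eGFR against the gestational reference intervals
#'
#' Computes the gestational eGFR from the measurement, looks up the week's
#' reference-interval row, and flags both analytes. Values on an interval
#' boundary count as within (closed intervals). SCr below its interval with
#' eGFR above suggests normal-to-exaggerated hyperfiltration; SCr above
#' with eGFR below flags blunted hyperfiltration (possible gestational
#' renal dysfunction or preeclampsia).
#'
#' @param scr Measured SCr, umol/L.
#' @param gw Gestational week, 4-41 (GW 0-3 returns a pre-implantation
#'   notice with no flags).
#' @param ri_table Data frame as from [make_ri_table()] or
#'   [ri_table_published()].
#' @param params An [egfr_parameters()].
#' @return An object of class `patient_report`: `gw`, `scr`, `egfr`,
#'   `scr_flag`, `egfr_flag`, and the RI bounds used.
#' @export
evaluate_patient <- function(scr, gw, ri_table = ri_table_published(),
                             params = egfr_parameters()) {
  if (scr <= 0) stop("`scr` must be > 0")
  if (gw < 0 || gw > 41) stop("`gw` must lie in [0, 41]")
  if (gw < 4) {
    message("pre-implantation period (GW 0-3): no gestational RI applies; ",
            "compare against the non-pregnant baseline instead")
    return(structure(list(gw = gw, scr = scr, egfr = NA_real_,
                          scr_flag = NA_character_, egfr_flag = NA_character_,
                          ri = NULL),
                     class = "patient_report"))
  }
  row <- ri_table[ri_table$gw == gw, ]
  if (nrow(row) != 1L) stop("no reference-interval row for GW ", gw)
  egfr <- suppressWarnings(gestational_egfr(scr, gw, params))
  structure(list(
    gw = gw, scr = scr, egfr = egfr,
    scr_flag = .flag_against(scr, row$scr_lower, row$scr_upper),
    egfr_flag = .flag_against(egfr, row$egfr_lower, row$egfr_upper),
    ri = row),
    class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat("patient report, GW ", x$gw, "\n", sep = "")
  if (is.na(x$scr_flag)) {
    cat("  pre-implantation period: no gestational flags\n")
    return(invisible(x))
  }
  cat(sprintf("  SCr  %6.1f umol/L  [%5.1f, %5.1f]  -> %s\n",
              x$scr, x$ri$scr_lower, x$ri$scr_upper, x$scr_flag))
  cat(sprintf("  eGFR %6.1f mL/min  [%5.1f, %5.1f]  -> %s\n",
              x$egfr, x$ri$egfr_lower, x$ri$egfr_upper, x$egfr_flag))
  invisible(x)
}
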