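# Verification against an external percentile table: per-GW differences
# between a reference study's SCr percentiles and this pipeline's curves,
# aggregated by GW, trimester and percentile. Differences are rounded to
# 0.1 umol/L before aggregation — that is the arithmetic that reproduces
# the published comparison.

#' Trimester of a gestational week
#'
#' Trimester 1 ends at GW 13 and trimester 2 at GW 27.
#'
#' @param gw Integer gestational week(s) in `[0, 41]`.
#' @return Integer 1, 2 or 3.
#' @export
trimester_of <- function(gw) {
  if (any(gw < 0 | gw > 41)) stop("gw must lie in [0, 41]")
  ifelse(gw <= 13, 1L, ifelse(gw <= 27, 2L, 3L))
}

#' External reference SCr percentiles (large Canadian pregnancy cohort)
#'
#' Per-GW 95th/75th/50th percentile SCr values (umol/L) reported from
#' direct measurement in ~244,000 pregnancies, shipped as a plain-text
#' fixture for verification of this package's curves.
#'
#' @return Data frame with columns `gw`, `percentile`, `value` (umol/L).
#' @export
harel_reference <- function() {
  tab <- published_comparison()
  data.frame(gw = tab$gw, percentile = tab$percentile,
             value = tab$reference)
}

#' Published verification inputs: reference and study percentile values
#'
#' The external reference percentiles side by side with the study's smoothed
#' percentile values at the same weeks, as printed; the derived difference
#' columns can be recomputed from these with [compare_to_reference()].
#'
#' @return Data frame with columns `gw`, `trimester`, `percentile`,
#'   `reference`, `study` (both umol/L).
#' @export
published_comparison <- function() {
  path <- system.file("extdata", "table2_verification_percentiles.csv",
                      package = "gestgfr")
  read.csv(path)
}

#' Compare study percentile curves (or values) against a reference table
#'
#' For every (GW, percentile) pair present in `reference`, computes the
#' signed difference `study - reference` (negative when the study value is
#' lower), rounded to 0.1 umol/L, then aggregates: the mean difference per
#' GW (over its percentiles), per trimester (over the per-GW means of its
#' member weeks) and per percentile (over all weeks). All aggregates are
#' means of the rounded per-row differences, rounded to 0.1.
#'
#' @param reference Data frame with columns `gw`, `percentile`, `value`
#'   (umol/L), e.g. [harel_reference()].
#' @param study Either a data frame with columns `gw`, `percentile`,
#'   `value`, or a named list of [polynomial_curve()] objects with names
#'   `p<percentile>` (e.g. `p95`, `p75`, `p50`) to be evaluated at the
#'   reference weeks. Weeks outside a curve's domain are skipped with a
#'   warning.
#' @return An object of class `ri_comparison`: list with `table` (per-row
#'   differences), `by_gw`, `by_trimester`, `by_percentile`.
#' @export
compare_to_reference <- function(reference, study) {
  ref <- data.frame(gw = reference$gw, percentile = reference$percentile,
                    reference = reference$value)
  if (is.data.frame(study)) {
    st <- data.frame(gw = study$gw, percentile = study$percentile,
                     study = study$value)
    tab <- merge(ref, st, by = c("gw", "percentile"))
    if (nrow(tab) < nrow(ref)) {
      warning(sprintf("%d reference rows had no matching study value and were skipped",
                      nrow(ref) - nrow(tab)))
    }
  } else {
    tab <- ref
    tab$study <- NA_real_
    for (p in unique(tab$percentile)) {
      crv <- study[[paste0("p", format(p))]]
      if (is.null(crv)) stop("no study curve for percentile ", p)
      rows <- tab$percentile == p
      inside <- tab$gw >= crv$domain[1] & tab$gw <= crv$domain[2]
      if (any(rows & !inside)) {
        warning("reference weeks outside the study-curve domain were skipped: GW ",
                paste(tab$gw[rows & !inside], collapse = ", "))
      }
      tab$study[rows & inside] <- round(predict(crv, tab$gw[rows & inside]), 1)
    }
    tab <- tab[!is.na(tab$study), , drop = FALSE]
  }
  tab$difference <- round(tab$study - tab$reference, 1)
  tab$trimester <- trimester_of(tab$gw)
  tab <- tab[order(tab$gw, -tab$percentile),
             c("gw", "trimester", "percentile", "reference", "study", "difference")]
  rownames(tab) <- NULL

  by_gw <- aggregate(difference ~ gw + trimester, data = tab,
                     function(d) round(mean(d), 1))
  names(by_gw)[3] <- "mean_difference"
  by_gw <- by_gw[order(by_gw$gw), ]
  rownames(by_gw) <- NULL

  by_tri <- aggregate(mean_difference ~ trimester, data = by_gw,
                      function(d) round(mean(d), 1))
  by_pct <- aggregate(difference ~ percentile, data = tab,
                      function(d) round(mean(d), 1))
  names(by_pct)[2] <- "mean_difference"
  by_pct <- by_pct[order(-by_pct$percentile), ]
  rownames(by_pct) <- NULL

  structure(list(table = tab, by_gw = by_gw, by_trimester = by_tri,
                 by_percentile = by_pct),
            class = "ri_comparison")
}

#' @export
print.ri_comparison <- function(x, ...) {
  cat("Comparison against external reference percentiles (umol/L)\n")
  cat("  mean difference by percentile:\n")
  print(x$by_percentile, row.names = FALSE)
  cat("  mean difference by trimester:\n")
  print(x$by_trimester, row.names = FALSE)
  invisible(x)
}
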