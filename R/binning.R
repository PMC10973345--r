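# Pooling gestational weeks into gestational periods (GPs) so each bin has
# enough measurements to resample.

#' Configuration of the GW-to-GP binning
#'
#' The first bin is always the pre-implantation period GW 0-3; the remaining
#' 38 weeks (GW 4-41) are covered by consecutive bins of width 3 or 4. The
#' default — five 4-week bins followed by six 3-week bins — yields 12 GPs,
#' wider bins where prenatal sampling is sparse.
#'
#' @param widths Integer vector of bin widths (each 3 or 4) covering GW 4-41;
#'   must sum to 38.
#' @param min_per_bin Minimum measurements a GP must hold (default 20, the
#'   CLSI minimum for reference-interval construction); under-filled bins
#'   are merged forward.
#' @return An object of class `binning_config`.
#' @export
binning_config <- function(widths = c(4L, 4L, 4L, 4L, 4L, 3L, 3L, 3L, 3L, 3L, 3L),
                           min_per_bin = 20L) {
  widths <- as.integer(widths)
  if (!all(widths %in% c(3L, 4L))) stop("bin widths must be 3 or 4")
  if (sum(widths) != 38L) stop("bin widths must cover GW 4-41 (sum to 38)")
  if (min_per_bin < 1L) stop("`min_per_bin` must be >= 1")
  structure(list(widths = widths, min_per_bin = as.integer(min_per_bin)),
            class = "binning_config")
}

# nominal bin bounds: [0,3] then the configured widths
.bin_bounds <- function(cfg) {
  hi <- 3L + cumsum(c(0L, cfg$widths))
  data.frame(lo = c(0L, hi[-length(hi)] + 1L), hi = c(3L, hi[-1]))
}

#' Pool SCr measurements into gestational periods
#'
#' Assigns every measurement to one nominal bin ([binning_config()]), drops
#' empty bins, and merges any bin holding fewer than `min_per_bin`
#' measurements into its successor (the last bin merges backward) until all
#' remaining GPs meet the minimum. The result partitions the input: GP sizes
#' sum to the number of measurements.
#'
#' @param measurements Data frame with columns `gw` and `scr` (as returned
#'   by [generate_cohort()] or [read_cohort()]).
#' @param cfg A [binning_config()].
#' @return List of `gestational_period` objects (class
#'   `gestational_periods`), each with fields `label`, `gw_lo`, `gw_hi`,
#'   `midpoint` and `values`.
#' @export
bin_into_periods <- function(measurements, cfg = binning_config()) {
  if (nrow(measurements) == 0L) stop("no measurements to bin")
  if (nrow(measurements) < cfg$min_per_bin) {
    stop(sprintf("cannot bin: %d measurements in total, fewer than min_per_bin = %d",
                 nrow(measurements), cfg$min_per_bin))
  }
  if (any(measurements$gw < 0 | measurements$gw > 41)) {
    stop("gestational weeks must lie in [0, 41]")
  }
  bounds <- .bin_bounds(cfg)
  idx <- findInterval(measurements$gw, bounds$lo)
  bins <- lapply(seq_len(nrow(bounds)), function(b) {
    list(gw_lo = bounds$lo[b], gw_hi = bounds$hi[b],
         values = measurements$scr[idx == b])
  })
  bins <- Filter(function(b) length(b$values) > 0, bins)

  # merge under-filled bins into their successor; final bin merges backward
  i <- 1L
  while (i <= length(bins)) {
    if (length(bins[[i]]$values) >= cfg$min_per_bin) { i <- i + 1L; next }
    j <- if (i < length(bins)) i + 1L else i - 1L
    if (j == 0L) break  # single under-filled bin: guarded above
    merged <- list(gw_lo = min(bins[[i]]$gw_lo, bins[[j]]$gw_lo),
                   gw_hi = max(bins[[i]]$gw_hi, bins[[j]]$gw_hi),
                   values = c(bins[[min(i, j)]]$values, bins[[max(i, j)]]$values))
    bins[[min(i, j)]] <- merged
    bins[[max(i, j)]] <- NULL
    i <- 1L  # re-scan from the start after a merge
  }

  out <- lapply(seq_along(bins), function(g) {
    b <- bins[[g]]
    structure(list(label = g, gw_lo = b$gw_lo, gw_hi = b$gw_hi,
                   midpoint = (b$gw_lo + b$gw_hi) / 2,
                   values = b$values),
              class = "gestational_period")
  })
  structure(out, class = "gestational_periods")
}

#' @export
print.gestational_periods <- function(x, ...) {
  cat(length(x), "gestational periods:\n")
  for (gp in x) {
    cat(sprintf("  GP%-2d GW %2d-%2d  n = %4d  median = %6.1f umol/L\n",
                gp$label, gp$gw_lo, gp$gw_hi, length(gp$values),
                median(gp$values)))
  }
  invisible(x)
}
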