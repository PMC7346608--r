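#' Exponential growth model for a dilution series
#'
#' Fluorescence expected at cycle `x` on the curve with dilution exponent `j`
#' under pure exponential amplification:
#' \deqn{y = y_0 E^x / D^j}
#' where `y0` is the cycle-0 signal of the most concentrated reaction
#' (`j = 0`), `E` the per-cycle amplification efficiency and `D` the serial
#' dilution factor.
#'
#' @param y0 Cycle-0 fluorescence (RFU) of the `j = 0` curve; `> 0`.
#' @param E Amplification efficiency, ideally in `[1, 2]`.
#' @param x Cycle number(s).
#' @param j Dilution exponent(s), `>= 0`; concentration is `c0 / D^j`.
#' @param D Dilution factor, `> 1` (default 2).
#' @return Expected fluorescence, vectorized over `x` and `j`.
#' @examples
#' exp_model_value(1, 2, x = 3, j = 1)   # 8 / 2 = 4
#' @export
exp_model_value <- function(y0, E, x, j = 0, D = 2) {
  stopifnot(is.numeric(y0), y0 > 0, is.numeric(E), E > 0,
            is.numeric(D), D > 1, all(j >= 0))
  y0 * E^x / D^j
}

#' Logistic (self-limiting) growth model
#'
#' Sigmoidal amplification curve in which the efficiency declines smoothly
#' from its baseline-region value `E0` as the signal approaches the plateau
#' `ymax`:
#' \deqn{y(x) = \frac{y_0 y_{max} E_0^x}{y_0 E_0^x + y_{max} - y_0}}
#'
#' Evaluated in the numerically stable form
#' `ymax / (1 + ((ymax - y0)/y0) E0^(-x))`, so large `x` does not overflow.
#'
#' @param y0 Cycle-0 fluorescence, `0 < y0 < ymax`.
#' @param ymax Plateau fluorescence (RFU).
#' @param E0 Baseline-region efficiency, `> 1`.
#' @param x Cycle number(s).
#' @return Expected fluorescence, vectorized over `x`.
#' @export
logistic_model_value <- function(y0, ymax, E0, x) {
  stopifnot(y0 > 0, ymax > y0, E0 > 1)
  ymax / (1 + ((ymax - y0) / y0) * E0^(-x))
}

#' Exponential growth zone (RFU window)
#'
#' The fluorescence window inside which amplification is treated as still
#' exponential.  The defaults, 20-180 RFU, are the window conventionally used
#' for full dilution-series analyses of curves plateauing near 600 RFU.
#'
#' @param lo,hi Inclusive lower/upper RFU bounds, `0 < lo < hi`.
#' @return An object of class `growth_zone`.
#' @export
growth_zone <- function(lo = 20, hi = 180) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo > 0, hi > lo)
  structure(list(lo = lo, hi = hi), class = "growth_zone")
}

#' Select growth-zone points from a dilution series
#'
#' For each curve, returns the first contiguous run of cycles whose
#' fluorescence lies inside the zone (bounds inclusive) and which is entered
#' from below (`y < lo` on the preceding cycle, or run starts at the first
#' recorded cycle).  Points recorded after a curve first exceeds the upper
#' bound are never included, so plateau re-entry and late noise cannot
#' contribute.  Curves contributing no points are skipped with a warning.
#'
#' @param series A [dilution_series()].
#' @param zone A [growth_zone()].
#' @return A `growth_points` data frame with columns `curve_index`, `well`,
#'   `j`, `x` (cycle) and `y` (RFU), ordered by `(curve_index, x)`, carrying
#'   the series dilution factor as attribute `dilution_factor`.
#' @export
select_growth_zone <- function(series, zone = growth_zone()) {
  stopifnot(inherits(series, "dilution_series"), inherits(zone, "growth_zone"))
  out <- vector("list", length(series$curves))
  for (ci in seq_along(series$curves)) {
    crv <- series$curves[[ci]]
    y <- crv$fluorescence
    x <- crv$cycles
    first_hi <- which(y > zone$hi)[1L]
    lim <- if (is.na(first_hi)) length(y) else first_hi - 1L
    run <- integer(0)
    if (lim >= 1L) {
      in_zone <- y >= zone$lo & y <= zone$hi
      starts <- which(in_zone[seq_len(lim)] &
                        (seq_len(lim) == 1L | c(FALSE, y[-length(y)] < zone$lo)[seq_len(lim)]))
      if (length(starts)) {
        s <- starts[1L]
        e <- s
        while (e < lim && in_zone[e + 1L]) e <- e + 1L
        run <- s:e
      }
    }
    if (!length(run)) {
      warning(sprintf("curve '%s' (j = %d) has no growth-zone points; skipped",
                      crv$well_id, crv$dilution_exponent))
      next
    }
    out[[ci]] <- data.frame(curve_index = ci, well = crv$well_id,
                            j = crv$dilution_exponent, x = x[run], y = y[run],
                            stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("no growth-zone data in any curve")
  pts <- do.call(rbind, out)
  rownames(pts) <- NULL
  structure(pts, dilution_factor = series$dilution_factor,
            class = c("growth_points", "data.frame"))
}

#' Construct growth points directly
#'
#' Low-level constructor used by the simulator and tests; bypasses zone
#' selection.
#'
#' @param j,x,y Dilution exponents, cycles and fluorescence values.
#' @param D Dilution factor attribute.
#' @param curve_index Optional curve index (defaults to `j + 1`).
#' @param well Optional well labels.
#' @return A `growth_points` data frame.
#' @export
growth_points <- function(j, x, y, D = 2, curve_index = NULL, well = NULL) {
  stopifnot(length(j) == length(x), length(x) == length(y))
  if (is.null(curve_index)) curve_index <- as.integer(factor(j))
  if (is.null(well)) well <- paste0("W", curve_index)
  structure(data.frame(curve_index = curve_index, well = well,
                       j = as.numeric(j), x = as.numeric(x), y = as.numeric(y),
                       stringsAsFactors = FALSE),
            dilution_factor = D, class = c("growth_points", "data.frame"))
}
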