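#' A single baselined amplification curve
#'
#' @param well_id Well label (character scalar).
#' @param dilution_exponent Integer `j >= 0`; the reaction concentration is
#'   `c0 / D^j`.
#' @param cycles Strictly increasing integer cycle numbers.
#' @param fluorescence Baselined RFU values (may be negative near zero).
#' @return An object of class `amp_curve`.
#' @export
amp_curve <- function(well_id, dilution_exponent, cycles, fluorescence) {
  stopifnot(is.character(well_id), length(well_id) == 1L,
            length(dilution_exponent) == 1L, dilution_exponent >= 0,
            dilution_exponent == round(dilution_exponent),
            length(cycles) == length(fluorescence))
  if (any(diff(cycles) <= 0)) stop("cycles must be strictly increasing")
  structure(list(well_id = well_id,
                 dilution_exponent = as.integer(dilution_exponent),
                 cycles = as.numeric(cycles),
                 fluorescence = as.numeric(fluorescence)),
            class = "amp_curve")
}

#' A dilution series of amplification curves
#'
#' @param curves List of [amp_curve()] objects.
#' @param dilution_factor Serial dilution factor `D > 1` shared by all curves
#'   (default 2).
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(curves, dilution_factor = 2) {
  stopifnot(is.list(curves), length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "amp_curve")),
            dilution_factor > 1)
  js <- vapply(curves, `[[`, integer(1), "dilution_exponent")
  wells <- vapply(curves, `[[`, character(1), "well_id")
  if (anyDuplicated(wells)) stop("duplicate well ids in series")
  structure(list(curves = curves[order(js, wells)],
                 dilution_factor = dilution_factor),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("<dilution_series> %d curve(s), dilution factor %g\n",
              length(x$curves), x$dilution_factor))
  for (crv in x$curves)
    cat(sprintf("  %-8s j=%d  %d cycles, RFU range [%.3g, %.3g]\n",
                crv$well_id, crv$dilution_exponent, length(crv$cycles),
                min(crv$fluorescence), max(crv$fluorescence)))
  invisible(x)
}

#' Read a dilution series from tidy (long) delimited text
#'
#' Expects a header with columns `well`, `dilution_exponent`, `cycle`,
#' `fluorescence` (extra columns are ignored).  Rows may arrive in any order;
#' they are grouped by well and sorted by cycle.
#'
#' @param path Path to a delimited text file.
#' @param dilution_factor Dilution factor of the series (default 2).
#' @param sep Field separator (default `","`).
#' @return A [dilution_series()].
#' @export
read_series <- function(path, dilution_factor = 2, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE)
  req <- c("well", "dilution_exponent", "cycle", "fluorescence")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop(sprintf("format error: missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric '%s' at data row %d ('%s')",
                   col, bad[1], raw[[col]][bad[1]]))
    v
  }
  df <- data.frame(well = raw$well,
                   dilution_exponent = num("dilution_exponent"),
                   cycle = num("cycle"),
                   fluorescence = num("fluorescence"),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("well", "cycle")]))
    stop("integrity error: duplicate (well, cycle) rows")
  curves <- lapply(split(df, df$well), function(g) {
    if (length(unique(g$dilution_exponent)) != 1L)
      stop(sprintf("integrity error: well '%s' has inconsistent dilution_exponent",
                   g$well[1]))
    g <- g[order(g$cycle), ]
    amp_curve(g$well[1], g$dilution_exponent[1], g$cycle, g$fluorescence)
  })
  dilution_series(unname(curves), dilution_factor = dilution_factor)
}

#' Write a dilution series as tidy CSV
#'
#' Inverse of [read_series()]: round-trips `(well, j, cycle, fluorescence)`
#' exactly.
#'
#' @param series A [dilution_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dilution_series"))
  rows <- lapply(series$curves, function(crv)
    data.frame(well = crv$well_id, dilution_exponent = crv$dilution_exponent,
               cycle = crv$cycles, fluorescence = crv$fluorescence,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a wide cycle-by-well fluorescence matrix to the tidy schema
#'
#' @param mat Numeric matrix, one row per cycle and one column per well.
#' @param dilution_exponents Integer vector, one per column.
#' @param cycles Cycle numbers (default `1:nrow(mat)`).
#' @param wells Well labels (default column names, else `W1..Wn`).
#' @return A tidy data frame with the [read_series()] columns.
#' @export
wide_to_long <- function(mat, dilution_exponents, cycles = seq_len(nrow(mat)),
                         wells = colnames(mat)) {
  mat <- as.matrix(mat)
  stopifnot(length(dilution_exponents) == ncol(mat),
            length(cycles) == nrow(mat))
  if (is.null(wells)) wells <- paste0("W", seq_len(ncol(mat)))
  data.frame(well = rep(wells, each = nrow(mat)),
             dilution_exponent = rep(dilution_exponents, each = nrow(mat)),
             cycle = rep(cycles, ncol(mat)),
             fluorescence = as.vector(mat), stringsAsFactors = FALSE)
}

.strip_class <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(lapply(x, identity)))
  if (is.list(x)) {
    cls <- class(x)[1]
    out <- lapply(x, .strip_class)
    if (!identical(cls, "list")) out <- c(list(.class = cls), out)
    return(out)
  }
  x
}

#' Write any result object as structured machine-readable text (JSON)
#'
#' Numbers are serialized at full double precision so that a read-back
#' reproduces every value exactly; the original S3 class is recorded in a
#' `.class` field.  Seeds stored on result objects are preserved, making
#' reports reproducible provenance records.
#'
#' @param result Any result object produced by this package (fit results,
#'   summaries, Monte Carlo results, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  jsonlite::write_json(.strip_class(result), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Read back a structured result file
#'
#' @param path Path written by [write_result()].
#' @return A list mirroring the original object (class tag in `$.class`).
#' @export
read_result <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
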