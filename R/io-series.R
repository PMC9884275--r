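#' Read a delimited time-series (or frequency-series) table
#'
#' First column is the axis (time or CPMG field), remaining columns are
#' traces labelled by the header.  Ragged rows are rejected by the parser
#' and a non-monotone time axis is a validation error.
#'
#' @param path CSV/TSV file with a one-line header.
#' @param xUnit "s", "h" or "Hz".
#' @param sep field separator (default auto: comma or whitespace).
#' @return A \linkS4class{SeriesTable}.
#' @export
readSeriesTable <- function(path, xUnit = "h", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl(",", readLines(path, n = 1L))) "," else ""
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(df) < 2L) stop("format error: no trace columns")
  SeriesTable(df[[1]], df[-1], xUnit = xUnit)
}

#' Write a SeriesTable as CSV
#' @param x a \linkS4class{SeriesTable}.
#' @param path output file.
#' @param xName header for the axis column (default the unit).
#' @return \code{path}, invisibly.
#' @export
writeSeriesTable <- function(x, path, xName = NULL) {
  if (is.null(xName)) xName <- switch(x@xUnit, h = "time_h", s = "time_s",
                                      Hz = "nu_hz")
  df <- cbind(setNames(data.frame(x@x), xName), x@columns)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert SeriesTable columns to KineticTrace objects
#' @param x a \linkS4class{SeriesTable} with a time axis.
#' @param kind "turbidity" or "tht".
#' @param condition condition label for all traces.
#' @return list of \linkS4class{KineticTrace}, one per column.
#' @export
asKineticTraces <- function(x, kind = "turbidity", condition = "") {
  if (!x@xUnit %in% c("s", "h")) stop("a time axis is required")
  tt <- if (x@xUnit == "s") x@x / 3600 else x@x
  lapply(names(x@columns), function(nm)
    KineticTrace(tt, x@columns[[nm]], replicateId = nm,
                 condition = condition, kind = kind))
}

#' Convert a frequency SeriesTable to DispersionCurve objects
#' @param x a \linkS4class{SeriesTable} with unit "Hz"; columns are R2eff
#'   per residue, column names are residue numbers.
#' @param tRelax constant-time relaxation delay (s).
#' @param fieldMHz spectrometer 1H frequency (MHz).
#' @param noiseSigmaR2 R2eff uncertainty (1/s).
#' @return list of \linkS4class{DispersionCurve}.
#' @export
asDispersionCurves <- function(x, tRelax = 0.06, fieldMHz = 800,
                               noiseSigmaR2 = 0.3) {
  if (x@xUnit != "Hz") stop("a frequency axis is required")
  lapply(names(x@columns), function(nm)
    DispersionCurve(as.integer(gsub("\\D", "", nm)), x@x, x@columns[[nm]],
                    tRelax = tRelax, fieldMHz = fieldMHz,
                    noiseSigmaR2 = noiseSigmaR2))
}
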