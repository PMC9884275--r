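#' Read a Sparky-style peak list
#'
#' Expects the common four-column dialect: assignment label, w1 (15N, ppm),
#' w2 (1H, ppm) and data height, with an optional header line.  Assignment
#' labels of the form \code{M323N-H} are parsed to residue number 323.
#' Negative heights are kept and flagged.
#'
#' @param path Sparky .list file.
#' @param noiseSigma spectral noise level to attach (standard deviation of
#'   the intensity distribution in signal-less spectral regions).
#' @return A \linkS4class{PeakTable}.
#' @export
readSparkyList <- function(path, noiseSigma) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- grep("^\\s*(Assignment|#)", lines, invert = TRUE, value = TRUE)
  if (!length(lines)) stop("format error: empty peak list")
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop(sprintf("line %d: expected 4 columns, got %d", i, length(tok)))
    m <- regmatches(tok[1], regexec("^[A-Za-z]+([0-9]+)N-H$", tok[1]))[[1]]
    if (length(m) < 2)
      stop(sprintf("line %d: unparsable assignment label '%s'", i, tok[1]))
    c(as.integer(m[2]), as.numeric(tok[3]), as.numeric(tok[2]),
      as.numeric(tok[4]))
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("residue_number", "h_ppm", "n_ppm", "intensity")
  PeakTable(df, noiseSigma = noiseSigma)
}

#' Write a PeakTable as a Sparky-style list
#' @param x a \linkS4class{PeakTable}.
#' @param path output file.
#' @param residueTypes optional named vector of one-letter codes by residue
#'   number for the assignment labels; defaults to "X".
#' @return \code{path}, invisibly.
#' @export
writeSparkyList <- function(x, path, residueTypes = NULL) {
  df <- x@peaks
  code <- rep("X", nrow(df))
  if (!is.null(residueTypes)) {
    hit <- match(as.character(df$residue_number), names(residueTypes))
    code[!is.na(hit)] <- residueTypes[hit[!is.na(hit)]]
  }
  lines <- c(" Assignment         w1         w2   Data Height",
             sprintf("%s%dN-H %10.3f %10.3f %14.6g", code,
                     df$residue_number, df$n_ppm, df$h_ppm, df$intensity))
  writeLines(lines, path)
  invisible(path)
}
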