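#' Create a SequenceRecord
#'
#' @param sequence one-letter amino-acid string; lowercase \code{m} marks
#'   methionine sulfoxide and is normalised to \code{M}.
#' @param id identifier.
#' @param offset full-protein number of the first residue (default 1).
#' @return A \linkS4class{SequenceRecord}.
#' @examples
#' pld <- SequenceRecord("GRFGG", id = "PLD-start", offset = 274)
#' residueNumbers(pld)
#' @export
SequenceRecord <- function(sequence, id = "seq", offset = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  s <- strsplit(sequence, "")[[1]]
  oxidized <- s == "m"
  s[oxidized] <- "M"
  bad <- which(!s %in% AA1)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d", s[bad[1]], bad[1]))
  new("SequenceRecord", id = id, sequence = paste(s, collapse = ""),
      offset = as.integer(offset), oxidized = oxidized)
}

#' Create a ShiftTable
#'
#' @param shifts data.frame with columns residue_number, residue_type,
#'   atom_name, shift (ppm); an optional logical column oxidized.
#' @param temperature sample temperature (K).
#' @param pH sample pH.
#' @param assumedConditions TRUE when the conditions were defaulted rather
#'   than read from the source.
#' @return A \linkS4class{ShiftTable}.
#' @export
ShiftTable <- function(shifts, temperature = 288, pH = 6.8,
                       assumedConditions = FALSE) {
  shifts <- as.data.frame(shifts)
  if (is.null(shifts$oxidized)) shifts$oxidized <- FALSE
  shifts$residue_number <- as.integer(shifts$residue_number)
  new("ShiftTable", shifts = shifts, temperature = temperature, pH = pH,
      assumedConditions = assumedConditions)
}

#' Create a PeakTable
#'
#' @param peaks data.frame with columns residue_number, h_ppm, n_ppm,
#'   intensity.
#' @param noiseSigma spectral noise level (> 0), estimated as the standard
#'   deviation of intensities in signal-less spectral regions.
#' @return A \linkS4class{PeakTable}.
#' @export
PeakTable <- function(peaks, noiseSigma) {
  peaks <- as.data.frame(peaks)
  if (is.null(peaks$flagged)) peaks$flagged <- peaks$intensity < 0
  peaks$residue_number <- as.integer(peaks$residue_number)
  new("PeakTable", peaks = peaks, noiseSigma = noiseSigma)
}

#' Create a SeriesTable
#' @param x numeric axis values.
#' @param columns data.frame (or named list) of traces aligned with x.
#' @param xUnit "s", "h" or "Hz".
#' @return A \linkS4class{SeriesTable}.
#' @export
SeriesTable <- function(x, columns, xUnit = "h")
  new("SeriesTable", x = as.numeric(x), xUnit = xUnit,
      columns = as.data.frame(columns))

#' Create a ModelEnsemble
#' @param atoms data.frame with residue_number, residue_type, atom_name.
#' @param coords numeric array n_atoms x 3 x n_conformers (Angstrom).
#' @param labels conformer ids (default "1".."N").
#' @return A \linkS4class{ModelEnsemble}.
#' @export
ModelEnsemble <- function(atoms, coords, labels = NULL) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$residue_type)) atoms$residue_type <- "UNK"
  if (is.null(labels)) labels <- as.character(seq_len(dim(coords)[3]))
  atoms$residue_number <- as.integer(atoms$residue_number)
  new("ModelEnsemble", atoms = atoms, coords = coords, labels = labels)
}

#' Create a DecaySeries
#' @param residue residue number.
#' @param delays relaxation delays (s).
#' @param intensities intensities at each delay.
#' @param noiseSigma spectral noise level.
#' @return A \linkS4class{DecaySeries}.
#' @export
DecaySeries <- function(residue, delays, intensities, noiseSigma)
  new("DecaySeries", residue = as.integer(residue), delays = delays,
      intensities = intensities, noiseSigma = noiseSigma)

#' Create a DispersionCurve
#' @param residue residue number.
#' @param nuCpmg CPMG fields (Hz).
#' @param r2eff effective rates (1/s).
#' @param tRelax constant-time relaxation delay (s).
#' @param fieldMHz spectrometer 1H frequency (MHz).
#' @param noiseSigmaR2 R2eff uncertainty (1/s).
#' @return A \linkS4class{DispersionCurve}.
#' @export
DispersionCurve <- function(residue, nuCpmg, r2eff, tRelax = 0.06,
                            fieldMHz = 800, noiseSigmaR2 = 0.3)
  new("DispersionCurve", residue = as.integer(residue), nuCpmg = nuCpmg,
      r2eff = r2eff, tRelax = tRelax, fieldMHz = fieldMHz,
      noiseSigmaR2 = noiseSigmaR2)

#' Create a KineticTrace
#' @param time time (hours).
#' @param signal A600 or ThT fluorescence.
#' @param replicateId replicate label.
#' @param condition condition label.
#' @param kind "turbidity" or "tht".
#' @return A \linkS4class{KineticTrace}.
#' @export
KineticTrace <- function(time, signal, replicateId = "r1", condition = "",
                         kind = "turbidity")
  new("KineticTrace", time = time, signal = signal,
      replicateId = replicateId, condition = condition, kind = kind)
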