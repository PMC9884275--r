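#' @import methods
#' @importFrom stats coef deviance lm median nls optim quantile rnorm sd
#'   setNames var
#' @importFrom utils read.table write.table
NULL

AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T",
         "V","W","Y")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
         "LYS","MET","PHE","PRO","SER","THR","VAL","TRP","TYR")
names(AA3) <- AA1

#' Amino-acid sequence with full-protein numbering
#'
#' Holds a one-letter amino-acid sequence together with the number of its
#' first residue in full-protein coordinates (e.g. 274 for the TDP-43
#' prion-like domain), so that per-residue results from every analysis line
#' up with the numbering used for the intact protein.  The lowercase letter
#' \code{m} is accepted on input as a methionine-sulfoxide alias; it is
#' normalised to \code{M} and the position recorded in the \code{oxidized}
#' slot.
#'
#' @slot id character identifier.
#' @slot sequence one-letter amino-acid string (standard 20 codes).
#' @slot offset integer, full-protein number of the first residue (>= 1).
#' @slot oxidized logical vector, one element per residue; \code{TRUE} marks
#'   methionine-sulfoxide positions.
#' @exportClass SequenceRecord
setClass("SequenceRecord",
  representation(id = "character", sequence = "character",
                 offset = "integer", oxidized = "logical"))

setValidity("SequenceRecord", function(object) {
  s <- strsplit(object@sequence, "")[[1]]
  bad <- which(!s %in% AA1)
  if (length(bad))
    return(sprintf("invalid residue '%s' at position %d", s[bad[1]], bad[1]))
  if (length(object@offset) != 1L || is.na(object@offset) ||
      object@offset < 1L)
    return("numbering offset must be a single integer >= 1")
  if (length(object@oxidized) != length(s))
    return("oxidized flag length must equal sequence length")
  TRUE
})

#' Per-residue, per-atom chemical shifts
#'
#' @slot shifts data.frame with columns \code{residue_number},
#'   \code{residue_type} (3-letter code), \code{atom_name}, \code{shift}
#'   (ppm) and logical \code{oxidized}.
#' @slot temperature sample temperature in K.
#' @slot pH sample pH.
#' @slot assumedConditions \code{TRUE} when temperature/pH were not present
#'   in the source file and defaults were recorded instead.
#' @exportClass ShiftTable
setClass("ShiftTable",
  representation(shifts = "data.frame", temperature = "numeric",
                 pH = "numeric", assumedConditions = "logical"))

setValidity("ShiftTable", function(object) {
  df <- object@shifts
  need <- c("residue_number", "residue_type", "atom_name", "shift")
  if (!all(need %in% names(df)))
    return(paste("shifts must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(df[c("residue_number", "atom_name")]))
    return("duplicate (residue_number, atom_name) pair")
  if (nrow(df) && any(!is.finite(df$shift)))
    return("non-finite chemical shift")
  TRUE
})

#' 2D amide peak list with intensities
#'
#' @slot peaks data.frame with columns \code{residue_number}, \code{h_ppm},
#'   \code{n_ppm}, \code{intensity} and logical \code{flagged} (negative
#'   heights are kept but flagged).
#' @slot noiseSigma spectral noise level, same units as intensity.
#' @exportClass PeakTable
setClass("PeakTable",
  representation(peaks = "data.frame", noiseSigma = "numeric"))

setValidity("PeakTable", function(object) {
  df <- object@peaks
  need <- c("residue_number", "h_ppm", "n_ppm", "intensity")
  if (!all(need %in% names(df)))
    return(paste("peaks must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(df$residue_number))
    return("duplicate residue number in peak list")
  if (!length(object@noiseSigma) || object@noiseSigma <= 0)
    return("noiseSigma must be > 0")
  TRUE
})

#' Aligned x/value table for time series and per-residue series
#'
#' @slot x numeric vector (time in s or h, or a frequency in Hz).
#' @slot xUnit one of "s", "h", "Hz".
#' @slot columns data.frame of traces, each column aligned with \code{x}.
#' @exportClass SeriesTable
setClass("SeriesTable",
  representation(x = "numeric", xUnit = "character", columns = "data.frame"))

setValidity("SeriesTable", function(object) {
  if (!object@xUnit %in% c("s", "h", "Hz"))
    return("xUnit must be one of 's', 'h', 'Hz'")
  if (nrow(object@columns) != length(object@x))
    return("columns must have one row per x value")
  if (ncol(object@columns) < 1L)
    return("at least one trace column is required")
  if (object@xUnit %in% c("s", "h") && any(diff(object@x) <= 0))
    return("time axis must be strictly increasing")
  TRUE
})

#' Multi-conformer coordinate ensemble
#'
#' All conformers share one (residue_number, atom_name) roster; coordinates
#' are stored as an atoms x 3 x conformers array in Angstrom.
#'
#' @slot atoms data.frame with columns \code{residue_number},
#'   \code{residue_type}, \code{atom_name}.
#' @slot coords numeric array \code{c(n_atoms, 3, n_conformers)}.
#' @slot labels character conformer ids.
#' @exportClass ModelEnsemble
setClass("ModelEnsemble",
  representation(atoms = "data.frame", coords = "array",
                 labels = "character"))

setValidity("ModelEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_conformers array")
  if (d[3] < 1L) return("at least one conformer is required")
  if (d[1] != nrow(object@atoms))
    return("coords first dimension must match the atom roster")
  if (length(object@labels) != d[3])
    return("one label per conformer is required")
  TRUE
})

#' Relaxation decay for one residue
#'
#' @slot residue residue number (full-protein numbering).
#' @slot delays relaxation delays in seconds, strictly increasing, >= 3.
#' @slot intensities peak intensities at each delay.
#' @slot noiseSigma spectral noise level in intensity units.
#' @exportClass DecaySeries
setClass("DecaySeries",
  representation(residue = "integer", delays = "numeric",
                 intensities = "numeric", noiseSigma = "numeric"))

setValidity("DecaySeries", function(object) {
  if (length(object@delays) < 3L) return("at least 3 delays are required")
  if (any(diff(object@delays) <= 0))
    return("delays must be strictly increasing")
  if (length(object@intensities) != length(object@delays))
    return("one intensity per delay is required")
  if (object@noiseSigma <= 0) return("noiseSigma must be > 0")
  TRUE
})

#' CPMG relaxation-dispersion curve for one residue
#'
#' @slot residue residue number.
#' @slot nuCpmg CPMG refocusing fields in Hz (0 allowed; it is treated as
#'   the zero-frequency limit of the exchange models).
#' @slot r2eff effective transverse relaxation rates in 1/s.
#' @slot tRelax total constant-time relaxation delay in s.
#' @slot fieldMHz spectrometer 1H frequency in MHz.
#' @slot noiseSigmaR2 uncertainty of each R2eff point in 1/s.
#' @exportClass DispersionCurve
setClass("DispersionCurve",
  representation(residue = "integer", nuCpmg = "numeric", r2eff = "numeric",
                 tRelax = "numeric", fieldMHz = "numeric",
                 noiseSigmaR2 = "numeric"))

setValidity("DispersionCurve", function(object) {
  if (any(object@nuCpmg < 0)) return("nuCpmg must be >= 0")
  if (length(object@r2eff) != length(object@nuCpmg))
    return("one R2eff per field is required")
  if (any(!is.finite(object@r2eff))) return("R2eff must be finite")
  if (object@tRelax <= 0) return("tRelax must be > 0")
  TRUE
})

#' Plate-reader kinetic trace (turbidity or ThT fluorescence)
#'
#' @slot time time in hours, strictly increasing, >= 2 points.
#' @slot signal A600 absorbance or ThT fluorescence (arbitrary units).
#' @slot replicateId replicate label.
#' @slot condition free-text condition label.
#' @slot kind "turbidity" or "tht".
#' @exportClass KineticTrace
setClass("KineticTrace",
  representation(time = "numeric", signal = "numeric",
                 replicateId = "character", condition = "character",
                 kind = "character"))

setValidity("KineticTrace", function(object) {
  if (length(object@time) < 2L) return("at least 2 time points are required")
  if (any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  if (length(object@signal) != length(object@time))
    return("one signal value per time point is required")
  if (!object@kind %in% c("turbidity", "tht"))
    return("kind must be 'turbidity' or 'tht'")
  TRUE
})
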