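#' @name accessors
#' @title Accessors for pldnmr data classes
#' @param x an object.
#' @param object an object (for show methods).
#' @return The slot contents; \code{residueNumbers} returns the
#'   full-protein residue numbers covered by the object.
NULL

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))
#' @rdname accessors
#' @export
setGeneric("shifts", function(x) standardGeneric("shifts"))
#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))
#' @rdname accessors
#' @export
setGeneric("seqString", function(x) standardGeneric("seqString"))
#' @rdname accessors
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))
#' @rdname accessors
#' @export
setGeneric("atomRoster", function(x) standardGeneric("atomRoster"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("oxidizedPositions", function(x)
  standardGeneric("oxidizedPositions"))

#' @rdname accessors
#' @export
setMethod("seqString", "SequenceRecord", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "SequenceRecord", function(x)
  seq.int(x@offset, length.out = nchar(x@sequence)))

#' @rdname accessors
#' @export
setMethod("oxidizedPositions", "SequenceRecord", function(x)
  residueNumbers(x)[x@oxidized])

#' @rdname accessors
#' @export
setMethod("shifts", "ShiftTable", function(x) x@shifts)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "ShiftTable", function(x)
  sort(unique(x@shifts$residue_number)))

#' @rdname accessors
#' @export
setMethod("conditions", "ShiftTable", function(x)
  c(temperature = x@temperature, pH = x@pH))

#' @rdname accessors
#' @export
setMethod("peaks", "PeakTable", function(x) x@peaks)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "PeakTable", function(x)
  sort(x@peaks$residue_number))

#' @rdname accessors
#' @export
setMethod("nConformers", "ModelEnsemble", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setMethod("atomRoster", "ModelEnsemble", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("coords", "ModelEnsemble", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "ModelEnsemble", function(x)
  sort(unique(x@atoms$residue_number)))

setMethod("show", "SequenceRecord", function(object) {
  rn <- residueNumbers(object)
  cat(sprintf("SequenceRecord '%s': %d residues (%d-%d)%s\n", object@id,
              nchar(object@sequence), rn[1], rn[length(rn)],
              if (any(object@oxidized))
                sprintf(", %d MetO", sum(object@oxidized)) else ""))
})

setMethod("show", "ShiftTable", function(object) {
  cat(sprintf(
    "ShiftTable: %d shifts, %d residues, %d atom types at %.1f K pH %.1f%s\n",
    nrow(object@shifts), length(residueNumbers(object)),
    length(unique(object@shifts$atom_name)), object@temperature, object@pH,
    if (object@assumedConditions) " (assumed)" else ""))
})

setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable: %d peaks, noise sigma %.3g\n",
              nrow(object@peaks), object@noiseSigma))
})

setMethod("show", "SeriesTable", function(object) {
  cat(sprintf("SeriesTable: %d points (%s), %d trace(s): %s\n",
              length(object@x), object@xUnit, ncol(object@columns),
              paste(utils::head(names(object@columns), 5), collapse = ", ")))
})

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble: %d conformer(s), %d atoms, %d residues\n",
              nConformers(object), nrow(object@atoms),
              length(residueNumbers(object))))
})

setMethod("show", "DecaySeries", function(object) {
  cat(sprintf("DecaySeries residue %d: %d delays (%.3g-%.3g s)\n",
              object@residue, length(object@delays), min(object@delays),
              max(object@delays)))
})

setMethod("show", "DispersionCurve", function(object) {
  cat(sprintf(
    "DispersionCurve residue %d: %d fields, T_relax %.3g s, %.0f MHz\n",
    object@residue, length(object@nuCpmg), object@tRelax, object@fieldMHz))
})

setMethod("show", "KineticTrace", function(object) {
  cat(sprintf("KineticTrace [%s] %s/%s: %d points over %.1f h\n",
              object@kind, object@condition, object@replicateId,
              length(object@time), max(object@time) - min(object@time)))
})
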