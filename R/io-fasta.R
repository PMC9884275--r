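#' Read a FASTA file into SequenceRecord objects
#'
#' Headers may carry an \code{offset=N} token giving the full-protein number
#' of the first residue (e.g. \code{>PLD offset=274}); without it numbering
#' starts at 1.  Lowercase \code{m} is read as methionine sulfoxide.
#'
#' @param path FASTA file.
#' @return list of \linkS4class{SequenceRecord}.
#' @examples
#' f <- system.file("extdata", "tdp43.fasta", package = "pldnmr")
#' recs <- readFasta(f)
#' recs[["PLD"]]
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # BStringSet keeps case: lowercase m marks methionine sulfoxide
  aa <- Biostrings::readBStringSet(path)
  if (!length(aa)) stop("format error: no FASTA records in ", path)
  recs <- lapply(seq_along(aa), function(i) {
    header <- names(aa)[i]
    toks <- strsplit(header, "\\s+")[[1]]
    id <- toks[1]
    off <- 1L
    hit <- grep("^offset=", toks, value = TRUE)
    if (length(hit)) off <- as.integer(sub("^offset=", "", hit[1]))
    SequenceRecord(as.character(aa[[i]]), id = id, offset = off)
  })
  names(recs) <- vapply(recs, function(r) r@id, "")
  recs
}

#' Write SequenceRecord objects to FASTA
#'
#' The numbering offset is preserved as an \code{offset=N} header token and
#' methionine-sulfoxide positions as lowercase \code{m}, so
#' \code{readFasta(writeFasta(x))} round-trips.
#'
#' @param records a SequenceRecord or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(records, path) {
  if (is(records, "SequenceRecord")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    s <- strsplit(r@sequence, "")[[1]]
    s[r@oxidized] <- "m"
    s <- paste(s, collapse = "")
    body <- substring(s, seq(1, nchar(s), 60),
                      pmin(seq(1, nchar(s), 60) + 59, nchar(s)))
    c(sprintf(">%s offset=%d", r@id, r@offset), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled TDP-43 sequences
#'
#' Returns the canonical human TDP-43 sequence (UniProt Q13148) or one of
#' the two fragments studied throughout the package: the prion-like domain
#' (PLD, residues 274-414) and the PLD_309 fragment (residues 309-350).
#'
#' @param which "TDP43", "PLD" or "PLD309".
#' @param oxidized if TRUE, all Met residues are flagged as methionine
#'   sulfoxide (the fully H2O2-oxidised state).
#' @return A \linkS4class{SequenceRecord}.
#' @examples
#' extinctionCoefficient(tdp43Sequence("PLD"))
#' @export
tdp43Sequence <- function(which = c("PLD", "TDP43", "PLD309"),
                          oxidized = FALSE) {
  which <- match.arg(which)
  f <- system.file("extdata", "tdp43.fasta", package = "pldnmr")
  rec <- readFasta(f)[[which]]
  if (oxidized) rec@oxidized <- strsplit(rec@sequence, "")[[1]] == "M"
  rec
}

#' Extract a sub-sequence in full-protein numbering
#' @param record a SequenceRecord.
#' @param region integer c(from, to), inclusive, full-protein numbering.
#' @return A \linkS4class{SequenceRecord} covering the region.
#' @export
subSequence <- function(record, region) {
  rn <- residueNumbers(record)
  keep <- rn >= region[1] & rn <= region[2]
  if (!any(keep)) stop("region outside sequence")
  s <- strsplit(record@sequence, "")[[1]][keep]
  out <- SequenceRecord(paste(s, collapse = ""),
                        id = sprintf("%s_%d-%d", record@id, region[1],
                                     region[2]),
                        offset = rn[keep][1])
  out@oxidized <- record@oxidized[keep]
  out
}
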