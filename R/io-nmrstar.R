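# Minimal NMR-STAR v3.1 handling: the assigned-chemical-shift loop and (when
# present) the sample-conditions loop.  No installed R package parses
# NMR-STAR, so the loop grammar needed here is implemented directly.

.metoAliases <- c("MSO", "MHO", "SME", "MEO")

.starTokens <- function(line) {
  line <- sub("#.*$", "", line)
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

# returns list(tags=character, rows=list of character vectors) for every
# loop_ ... stop_ block in the file
.starLoops <- function(lines) {
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, .starTokens(lines[i])[1])
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && trimws(lines[i]) != "stop_") {
        tok <- .starTokens(lines[i])
        if (length(tok)) rows[[length(rows) + 1L]] <- tok
        i <- i + 1L
      }
      loops[[length(loops) + 1L]] <- list(tags = tags, rows = rows)
    }
    i <- i + 1L
  }
  loops
}

#' Read assigned chemical shifts from an NMR-STAR v3.1 file
#'
#' Parses the \code{_Atom_chem_shift} loop of a BMRB-style deposit.  Sample
#' temperature and pH are taken from a \code{_Sample_condition_variable}
#' loop when present; otherwise the defaults 288 K / pH 6.8 are recorded
#' and flagged as assumed.  Nonstandard methionine-sulfoxide residue codes
#' are normalised to MET with the \code{oxidized} column set.
#'
#' @param path NMR-STAR file.
#' @return A \linkS4class{ShiftTable}.
#' @export
readNmrStarShifts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  loops <- .starLoops(lines)
  shiftLoop <- NULL
  condLoop <- NULL
  for (lp in loops) {
    if (any(grepl("^_Atom_chem_shift\\.", lp$tags))) shiftLoop <- lp
    if (any(grepl("^_Sample_condition_variable\\.", lp$tags))) condLoop <- lp
  }
  if (is.null(shiftLoop))
    stop("format error: no assigned-chemical-shift loop in ", path)
  tags <- sub("^_Atom_chem_shift\\.", "", shiftLoop$tags)
  idx <- function(nm) {
    j <- match(nm, tags)
    if (all(is.na(j))) stop("format error: missing tag ", nm[1])
    j[!is.na(j)][1]
  }
  iSeq <- idx(c("Seq_ID", "Comp_index_ID"))
  iComp <- idx("Comp_ID")
  iAtom <- idx("Atom_ID")
  iVal <- idx("Val")
  rows <- shiftLoop$rows
  comp <- toupper(vapply(rows, `[`, "", iComp))
  oxidized <- comp %in% .metoAliases
  comp[oxidized] <- "MET"
  unknown <- !comp %in% AA3
  if (any(unknown))
    stop("unknown residue code: ", comp[which(unknown)[1]])
  df <- data.frame(
    residue_number = as.integer(vapply(rows, `[`, "", iSeq)),
    residue_type = comp,
    atom_name = vapply(rows, `[`, "", iAtom),
    shift = as.numeric(vapply(rows, `[`, "", iVal)),
    oxidized = oxidized)
  temperature <- 288
  pH <- 6.8
  assumed <- TRUE
  if (!is.null(condLoop)) {
    ctags <- sub("^_Sample_condition_variable\\.", "", condLoop$tags)
    iT <- match("Type", ctags)
    iV <- match("Val", ctags)
    if (!is.na(iT) && !is.na(iV)) {
      typ <- tolower(vapply(condLoop$rows, `[`, "", iT))
      val <- as.numeric(vapply(condLoop$rows, `[`, "", iV))
      if ("temperature" %in% typ) {
        temperature <- val[match("temperature", typ)]
        assumed <- FALSE
      }
      if ("ph" %in% typ) {
        pH <- val[match("ph", typ)]
        assumed <- FALSE
      }
    }
  }
  ShiftTable(df, temperature = temperature, pH = pH,
             assumedConditions = assumed)
}

#' Write a ShiftTable as a minimal NMR-STAR v3.1 file
#'
#' Emits a sample-conditions loop and an assigned-chemical-shift loop;
#' methionine-sulfoxide entries are written with the MSO residue code so
#' that \code{readNmrStarShifts(writeNmrStarShifts(x))} round-trips.
#'
#' @param x a \linkS4class{ShiftTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNmrStarShifts <- function(x, path) {
  df <- x@shifts
  comp <- df$residue_type
  comp[df$oxidized & comp == "MET"] <- "MSO"
  lines <- c(
    "data_pldnmr_shifts", "",
    "loop_",
    "  _Sample_condition_variable.Type",
    "  _Sample_condition_variable.Val",
    sprintf("  temperature %g", x@temperature),
    sprintf("  pH %g", x@pH),
    "stop_", "",
    "loop_",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    sprintf("  %d %s %s %.4f", df$residue_number, comp, df$atom_name,
            df$shift),
    "stop_")
  writeLines(lines, path)
  invisible(path)
}
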