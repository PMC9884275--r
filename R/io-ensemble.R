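#' Read a multi-model PDB or mmCIF file as a ModelEnsemble
#'
#' PDB files are parsed with \pkg{bio3d}; mmCIF files (detected by the
#' \code{.cif} extension or a leading \code{data_} block with an
#' \code{_atom_site} loop) with a minimal reader of the \code{_atom_site}
#' loop.  MODEL blocks become conformers and the (residue, atom) roster is
#' checked for consistency across conformers.
#'
#' @param path structure file.
#' @return A \linkS4class{ModelEnsemble}.
#' @export
readModelEnsemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.cif$", path, ignore.case = TRUE))
    return(.readCifEnsemble(path))
  .pdbRosterCheck(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  atoms <- data.frame(residue_number = as.integer(at$resno),
                      residue_type = at$resid, atom_name = at$elety)
  nModels <- nrow(pdb$xyz)
  sel <- which(pdb$atom$type == "ATOM")
  xyzIdx <- as.vector(t(cbind(3 * (sel - 1) + 1, 3 * (sel - 1) + 2,
                              3 * (sel - 1) + 3)))
  co <- array(NA_real_, c(nrow(atoms), 3, nModels))
  for (m in seq_len(nModels))
    co[, , m] <- matrix(pdb$xyz[m, xyzIdx], ncol = 3, byrow = TRUE)
  .buildEnsemble(atoms, co, as.character(seq_len(nModels)))
}

# bio3d keeps one shared atom table for all MODEL blocks, so roster
# differences between blocks must be caught on the raw records first
.pdbRosterCheck <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2) return(invisible(TRUE))
  ends <- grep("^ENDMDL", lines)
  rosters <- lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    at <- grep("^ATOM  ", blk, value = TRUE)
    paste(trimws(substr(at, 13, 16)), trimws(substr(at, 23, 26)))
  })
  for (i in seq_along(rosters)[-1])
    if (!identical(rosters[[i]], rosters[[1]]))
      stop("validation error: conformer ", i,
           " differs in atom roster from conformer 1")
  invisible(TRUE)
}

# mmCIF _atom_site loop; conformers split on pdbx_PDB_model_num
.readCifEnsemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loops <- .starLoops(lines)
  lp <- NULL
  for (l in loops) if (any(grepl("^_atom_site\\.", l$tags))) lp <- l
  if (is.null(lp)) stop("format error: no _atom_site loop in ", path)
  tags <- sub("^_atom_site\\.", "", lp$tags)
  g <- function(nm) {
    j <- match(nm, tags)
    j[!is.na(j)][1]
  }
  iGrp <- g("group_PDB")
  iAtom <- g(c("label_atom_id", "auth_atom_id"))
  iComp <- g(c("label_comp_id", "auth_comp_id"))
  iSeq <- g(c("auth_seq_id", "label_seq_id"))
  iX <- g("Cartn_x"); iY <- g("Cartn_y"); iZ <- g("Cartn_z")
  iMod <- g("pdbx_PDB_model_num")
  if (any(is.na(c(iAtom, iComp, iSeq, iX, iY, iZ))))
    stop("format error: incomplete _atom_site loop")
  rows <- lp$rows
  if (!is.na(iGrp))
    rows <- rows[vapply(rows, `[`, "", iGrp) == "ATOM"]
  mod <- if (is.na(iMod)) rep("1", length(rows)) else
    vapply(rows, `[`, "", iMod)
  models <- unique(mod)
  byModel <- split(rows, factor(mod, levels = models))
  first <- byModel[[1]]
  atoms <- data.frame(
    residue_number = as.integer(vapply(first, `[`, "", iSeq)),
    residue_type = vapply(first, `[`, "", iComp),
    atom_name = gsub('"', "", vapply(first, `[`, "", iAtom)))
  co <- array(NA_real_, c(nrow(atoms), 3, length(models)))
  for (m in seq_along(models)) {
    rws <- byModel[[m]]
    if (length(rws) != nrow(atoms))
      stop("validation error: conformer ", models[m],
           " has a different atom roster")
    co[, 1, m] <- as.numeric(vapply(rws, `[`, "", iX))
    co[, 2, m] <- as.numeric(vapply(rws, `[`, "", iY))
    co[, 3, m] <- as.numeric(vapply(rws, `[`, "", iZ))
  }
  .buildEnsemble(atoms, co, models)
}

.buildEnsemble <- function(atoms, co, labels) {
  key <- paste(atoms$residue_number, atoms$atom_name)
  nAtoms <- nrow(atoms)
  # bio3d concatenates models over a shared atom table; roster mismatches
  # across MODEL blocks surface as repeated keys within one conformer
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("validation error: conformers differ in atom roster near ", dup)
  }
  if (any(!is.finite(co))) stop("validation error: missing coordinates")
  ModelEnsemble(atoms, co, labels)
}

#' Write a ModelEnsemble as a multi-model PDB file
#' @param x a \linkS4class{ModelEnsemble}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModelEnsemble <- function(x, path) {
  atoms <- x@atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(nConformers(x))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    nm <- atoms$atom_name
    nm4 <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), sprintf("%-4s", nm))
    writeLines(sprintf(
      "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(atoms)), nm4, substr(atoms$residue_type, 1, 3),
      atoms$residue_number, x@coords[, 1, m], x@coords[, 2, m],
      x@coords[, 3, m]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
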