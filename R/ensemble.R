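# Ensemble geometry: iterative mean-structure superposition (Kabsch
# rotations) and RMSD-to-mean convergence statistics.

.kabschRotation <- function(P, Q) {
  # optimal rotation mapping P onto Q, both centred
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

.selectAtoms <- function(e, region, atoms) {
  which(e@atoms$residue_number >= region[1] &
          e@atoms$residue_number <= region[2] &
          e@atoms$atom_name %in% atoms)
}

#' Superpose a conformer ensemble onto its mean structure
#'
#' Iterative mean-structure superposition: every conformer is rigid-body
#' fitted (optimal least-squares Kabsch rotation after centroid removal)
#' onto the current mean of the selected atoms, the mean is recomputed,
#' and the cycle repeats until the mean moves by less than \code{tol}
#' (RMS displacement in Angstrom).  The returned ensemble carries the full
#' atom set transformed by the alignment computed on the selection.
#'
#' @param e a \linkS4class{ModelEnsemble}.
#' @param region integer c(from, to) alignment region in full-protein
#'   numbering (default the short helix 324-332).
#' @param atoms backbone atom selection (default heavy backbone:
#'   N, CA, C, O).
#' @param tol convergence threshold on the mean displacement (Angstrom).
#' @return list with \code{ensemble} (aligned \linkS4class{ModelEnsemble}),
#'   \code{meanCoords} (selection atoms x 3), \code{selection} indices,
#'   \code{region}, \code{atoms}, \code{iterations}.
#' @export
superposeEnsemble <- function(e, region = c(324, 332),
                              atoms = c("N", "CA", "C", "O"),
                              tol = 1e-6) {
  sel <- .selectAtoms(e, region, atoms)
  if (length(sel) < 3)
    stop("fewer than 3 atoms in the alignment selection; ",
         "rotation underdetermined")
  nM <- nConformers(e)
  co <- e@coords
  # seed the iteration with the first conformer: the raw coordinate mean
  # of arbitrarily oriented conformers can be degenerate
  meanSel <- co[sel, , 1]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mcent <- colMeans(meanSel)
    M0 <- sweep(meanSel, 2, mcent)
    for (m in seq_len(nM)) {
      P <- co[sel, , m]
      pc <- colMeans(P)
      R <- .kabschRotation(sweep(P, 2, pc), M0)
      co[, , m] <- sweep(sweep(co[, , m], 2, pc) %*% R, 2, mcent, `+`)
    }
    newMean <- apply(co[sel, , , drop = FALSE], c(1, 2), mean)
    shift <- sqrt(mean((newMean - meanSel)^2))
    meanSel <- newMean
    if (shift < tol || iter >= 100L) break
  }
  aligned <- e
  aligned@coords <- co
  list(ensemble = aligned, meanCoords = meanSel, selection = sel,
       region = region, atoms = atoms, iterations = iter)
}

#' RMSD of each conformer to the mean coordinates
#'
#' Per-conformer root-mean-square deviation of the selected atoms from the
#' converged mean structure of a superposition, and their ensemble
#' average - the standard convergence statistic for NMR ensembles.
#'
#' @param sup result of \code{\link{superposeEnsemble}}.
#' @param region optional scoring region c(from, to); defaults to the
#'   alignment region.
#' @param atoms optional scoring atom set; defaults to the alignment set.
#' @return list with perConformer (Angstrom, named by conformer label) and
#'   average.
#' @export
rmsdToMean <- function(sup, region = NULL, atoms = NULL) {
  e <- sup$ensemble
  sel <- if (is.null(region) && is.null(atoms)) sup$selection else
    .selectAtoms(e, if (is.null(region)) sup$region else region,
                 if (is.null(atoms)) sup$atoms else atoms)
  if (!length(sel)) stop("empty scoring selection")
  co <- e@coords[sel, , , drop = FALSE]
  mn <- apply(co, c(1, 2), mean)
  per <- vapply(seq_len(nConformers(e)), function(m)
    sqrt(mean(rowSums((co[, , m] - mn)^2))), 0)
  names(per) <- e@labels
  list(perConformer = per, average = mean(per))
}
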