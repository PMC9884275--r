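# Seeded synthetic-data generators.  Each generator produces objects with
# the statistical structure the corresponding analysis stage assumes
# (Gaussian noise throughout, matching the Monte-Carlo error treatment of
# the analyses) and can emit through the package's format writers so the
# readers are exercised alongside.

#' Synthetic chemical-shift dataset with a planted helix
#'
#' Builds the random-coil Calpha/Cbeta reference for the sequence at the
#' given conditions, adds \code{population} x 3.1 ppm to Calpha inside
#' \code{helixRegion}, and Gaussian jitter (sd \code{sigma}) to every
#' shift.  Closing the loop through \code{\link{secondaryShifts}} and
#' \code{\link{helicalPopulation}} recovers \code{population}.
#'
#' @param record a \linkS4class{SequenceRecord}.
#' @param helixRegion integer c(from, to) in full-protein numbering.
#' @param population planted helical population in [0, 1].
#' @param seed integer seed.
#' @param sigma shift jitter in ppm (default 0.02).
#' @param temperature,pH sample conditions for the reference.
#' @param path optional file; when given the table is written as NMR-STAR
#'   via \code{\link{writeNmrStarShifts}} and the path returned.
#' @return A \linkS4class{ShiftTable} (or \code{path}).
#' @export
genShiftDataset <- function(record, helixRegion, population, seed = 1,
                            sigma = 0.02, temperature = 288, pH = 6.8,
                            path = NULL) {
  if (population < 0 || population > 1)
    stop("population must be in [0, 1]")
  rn <- residueNumbers(record)
  if (helixRegion[1] < rn[1] || helixRegion[2] > rn[length(rn)])
    stop("helix region outside the sequence")
  ref <- randomCoilReference(record, temperature, pH,
                             atoms = c("CA", "CB"))
  df <- ref@shifts
  set.seed(seed)
  inHelix <- df$atom_name == "CA" & df$residue_number >= helixRegion[1] &
    df$residue_number <= helixRegion[2]
  df$shift <- df$shift + ifelse(inHelix, population * 3.1, 0) +
    rnorm(nrow(df), 0, sigma)
  out <- ShiftTable(df, temperature = temperature, pH = pH)
  if (!is.null(path)) {
    writeNmrStarShifts(out, path)
    return(path)
  }
  out
}

#' Synthetic monoexponential decay series
#'
#' \eqn{I(t) = e^{-Rt} + N(0, \sigma)} per residue at the given delay
#' schedule.
#'
#' @param residues residue numbers.
#' @param rates true decay rates (1/s), recycled to length(residues).
#' @param delays delay schedule in s (default the seven R1 delays 20-1600
#'   ms).
#' @param sigma Gaussian noise sd.
#' @param seed integer seed.
#' @return list of \linkS4class{DecaySeries}.
#' @export
genDecaySeries <- function(residues, rates,
                           delays = c(0.02, 0.06, 0.15, 0.24, 0.46, 0.8,
                                      1.6),
                           sigma = 0.02, seed = 1) {
  rates <- rep_len(rates, length(residues))
  set.seed(seed)
  lapply(seq_along(residues), function(i) {
    I <- exp(-rates[i] * delays) + rnorm(length(delays), 0, sigma)
    DecaySeries(residues[i], delays, I, noiseSigma = max(sigma, 1e-12))
  })
}

#' Synthetic CPMG dispersion curves from the Bloch-McConnell propagator
#'
#' Forward-simulates two-state exchange with the numerical
#' \code{\link{blochMcConnellR2eff}} propagator (not the closed-form
#' models that \code{\link{fitDispersion}} fits) and adds Gaussian noise.
#'
#' @param kex exchange rate (1/s).
#' @param pB minor-state population.
#' @param dwPpm per-residue 15N shift differences (ppm), named by residue
#'   number or paired with \code{residues}.
#' @param r20 intrinsic R2 (1/s), recycled.
#' @param residues residue numbers (default names of dwPpm, else 1..n).
#' @param fields CPMG fields in Hz.
#' @param tRelax constant-time delay (s).
#' @param fieldMHz spectrometer 1H frequency (MHz).
#' @param sigma Gaussian noise sd on R2eff (1/s).
#' @param seed integer seed.
#' @return list of \linkS4class{DispersionCurve}.
#' @export
genDispersionCurves <- function(kex, pB, dwPpm, r20 = 8,
                                residues = NULL,
                                fields = defaultCpmgFields(),
                                tRelax = 0.06, fieldMHz = 800,
                                sigma = 0.3, seed = 1) {
  n <- length(dwPpm)
  if (is.null(residues))
    residues <- if (!is.null(names(dwPpm))) as.integer(names(dwPpm)) else
      seq_len(n)
  r20 <- rep_len(r20, n)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    truth <- blochMcConnellR2eff(fields, kex, pB, dwPpm[i], r20[i],
                                 fieldMHz, tRelax)
    DispersionCurve(residues[i], fields,
                    truth + rnorm(length(fields), 0, sigma),
                    tRelax = tRelax, fieldMHz = fieldMHz,
                    noiseSigmaR2 = max(sigma, 1e-12))
  })
}

#' Synthetic plate-reader kinetic traces
#'
#' Logistic traces \eqn{y_0 + A/(1 + e^{-k(t - t_{1/2})})} sampled every
#' \code{dt} hours over \code{horizon} hours with independent Gaussian
#' noise per replicate (the 15-min/96-h plate-reader schedule by default).
#'
#' @param kind "turbidity" or "tht".
#' @param y0 baseline signal.
#' @param A transition amplitude.
#' @param k rate (1/h).
#' @param tHalf half-completion time (h); a warning is issued when it lies
#'   beyond the horizon.
#' @param dt sampling interval (h), default 0.25.
#' @param horizon trace length (h), default 96.
#' @param sigma Gaussian noise sd.
#' @param seed integer seed.
#' @param nReplicates number of replicate traces.
#' @return list of \linkS4class{KineticTrace}.
#' @export
genKineticTrace <- function(kind = c("turbidity", "tht"), y0 = 0.05,
                            A = 1, k = 0.5, tHalf = 20, dt = 0.25,
                            horizon = 96, sigma = 0.02, seed = 1,
                            nReplicates = 1) {
  kind <- match.arg(kind)
  if (horizon <= tHalf)
    warning("horizon does not reach the half-completion time")
  tt <- seq(0, horizon, by = dt)
  set.seed(seed)
  lapply(seq_len(nReplicates), function(r)
    KineticTrace(tt, .logistic(tt, y0, A, k, tHalf) +
                   rnorm(length(tt), 0, sigma),
                 replicateId = sprintf("r%d", r), condition = "synthetic",
                 kind = kind))
}

#' Synthetic conformer ensemble
#'
#' A template structure plus per-conformer Gaussian atomic displacements
#' of root-mean-square magnitude \code{spread}, followed by a random
#' rigid-body transform per conformer (so superposition is actually
#' exercised).
#'
#' @param nConformers number of conformers (>= 1).
#' @param nAtoms atoms in the template.
#' @param spread RMS atomic displacement in Angstrom (>= 0).
#' @param seed integer seed.
#' @param startResidue residue number of the first template position.
#' @param atomNames atom names cycled along the template (default "CA"
#'   only; use c("N","CA","C","O") for a backbone-like roster, one
#'   residue per group of four).
#' @return A \linkS4class{ModelEnsemble}.
#' @export
genToyEnsemble <- function(nConformers, nAtoms, spread, seed = 1,
                           startResidue = 1L, atomNames = "CA") {
  stopifnot(nConformers >= 1, spread >= 0)
  set.seed(seed)
  nPer <- length(atomNames)
  resno <- startResidue + (seq_len(nAtoms) - 1) %/% nPer
  atoms <- data.frame(residue_number = resno, residue_type = "ALA",
                      atom_name = rep_len(atomNames, nAtoms))
  # loose-helix template: non-degenerate, realistic spacing
  i <- seq_len(nAtoms)
  template <- cbind(2.3 * cos(i), 2.3 * sin(i), 1.5 * i / nPer)
  co <- array(NA_real_, c(nAtoms, 3, nConformers))
  for (m in seq_len(nConformers)) {
    disp <- matrix(rnorm(nAtoms * 3, 0, spread / sqrt(3)), ncol = 3)
    X <- template + disp
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    co[, , m] <- sweep(X %*% Q, 2, stats::runif(3, -5, 5), `+`)
  }
  ModelEnsemble(atoms, co, as.character(seq_len(nConformers)))
}

#' @importFrom stats runif
NULL
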