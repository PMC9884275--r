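# Chemical-shift-derived analyses: secondary shifts, helical population,
# chemical-shift perturbation, intensity-broadening profiles and HNHA
# J couplings.

# empirical Calpha secondary shift of a fully formed alpha helix, ppm
.helixCaFull <- 3.1

#' Secondary chemical shifts
#'
#' Computes per-residue \eqn{\Delta C\alpha = C\alpha_{obs} -
#' C\alpha_{ref}}, \eqn{\Delta C\beta} and the combined
#' \eqn{\Delta C\alpha - \Delta C\beta}.  Positive combined values indicate
#' alpha-helical conformations, negative values beta-strand.  Only residues
#' with both an observed and a reference value for an atom carry that
#' delta.
#'
#' @param observed a \linkS4class{ShiftTable} of experimental shifts.
#' @param reference a \linkS4class{ShiftTable}, typically from
#'   \code{\link{randomCoilReference}} at the same conditions.
#' @param maskOxidizedMet drop methionine-sulfoxide residues from the
#'   output (no random-coil reference exists for the modified residue, so
#'   their deltas are not interpretable).
#' @return data.frame with columns residue_number, d_ca, d_cb, d_ca_cb;
#'   attribute \code{reference_conditions} carries temperature and pH.
#' @export
secondaryShifts <- function(observed, reference, maskOxidizedMet = FALSE) {
  obs <- observed@shifts
  ref <- reference@shifts
  merge1 <- function(atom) {
    o <- obs[obs$atom_name == atom, c("residue_number", "shift", "oxidized")]
    r <- ref[ref$atom_name == atom, c("residue_number", "shift")]
    m <- merge(o, r, by = "residue_number", suffixes = c("_obs", "_ref"))
    data.frame(residue_number = m$residue_number,
               delta = m$shift_obs - m$shift_ref, oxidized = m$oxidized)
  }
  ca <- merge1("CA")
  cb <- merge1("CB")
  if (!nrow(ca) && !nrow(cb))
    stop("no residues shared between observed and reference tables")
  res <- sort(unique(c(ca$residue_number, cb$residue_number)))
  out <- data.frame(
    residue_number = res,
    d_ca = ca$delta[match(res, ca$residue_number)],
    d_cb = cb$delta[match(res, cb$residue_number)],
    oxidized = res %in% c(ca$residue_number[ca$oxidized],
                          cb$residue_number[cb$oxidized]))
  out$d_ca_cb <- out$d_ca - out$d_cb
  if (maskOxidizedMet) out <- out[!out$oxidized, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_conditions") <- conditions(reference)
  out
}

#' Helical population from Calpha secondary shifts
#'
#' The mean \eqn{\Delta C\alpha} over a region, divided by the +3.1 ppm
#' expected for a 100\% alpha-helical conformer and clamped to [0, 1].
#' Uses \eqn{\Delta C\alpha} only (not the combined value), the convention
#' under which the +3.1 ppm benchmark is defined.
#'
#' @param profile data.frame from \code{\link{secondaryShifts}}.
#' @param region integer c(from, to), inclusive, full-protein numbering.
#' @return list with \code{population}, \code{meanDeltaCa} and the
#'   per-residue terms used.
#' @export
helicalPopulation <- function(profile, region) {
  sel <- profile$residue_number >= region[1] &
    profile$residue_number <= region[2] & !is.na(profile$d_ca)
  if (!any(sel)) stop("empty region")
  if (sum(sel) < 3)
    stop("need at least 3 residues with Calpha deltas in the region")
  terms <- profile[sel, c("residue_number", "d_ca")]
  m <- mean(terms$d_ca)
  list(population = min(max(m / .helixCaFull, 0), 1), meanDeltaCa = m,
       perResidue = terms)
}

#' Amide chemical-shift perturbation between two states
#'
#' \eqn{CSP = \sqrt{\Delta\delta_{1H}^2 + (\Delta\delta_{15N} \cdot s)^2}}
#' with the 15N dimension scaled by \code{nScale} (default 1/5).  Residues
#' present in only one table are reported with NA, not zero.
#'
#' @param a,b \linkS4class{PeakTable}s of the two states.
#' @param nScale 15N scaling factor.
#' @return data.frame residue_number, d_h, d_n, csp (NA when missing in
#'   either state).
#' @export
chemicalShiftPerturbation <- function(a, b, nScale = 1 / 5) {
  pa <- a@peaks; pb <- b@peaks
  res <- sort(unique(c(pa$residue_number, pb$residue_number)))
  ia <- match(res, pa$residue_number)
  ib <- match(res, pb$residue_number)
  if (!any(!is.na(ia) & !is.na(ib)))
    stop("no residues shared between the two peak tables")
  dh <- pa$h_ppm[ia] - pb$h_ppm[ib]
  dn <- pa$n_ppm[ia] - pb$n_ppm[ib]
  data.frame(residue_number = res, d_h = dh, d_n = dn,
             csp = sqrt(dh^2 + (dn * nScale)^2))
}

#' Intensity-ratio (broadening) and reverse-decay profiles
#'
#' Both tables are scaled by the median intensity over a normalisation
#' region, then the per-residue ratio \eqn{r = I_{state}/I_{ref}} and the
#' reverse value \eqn{1 - r} (floored at 0 for reporting) are computed.
#' Signal loss (small r, large reverse) marks residues broadened by
#' self-association or partner binding.
#'
#' @param state \linkS4class{PeakTable} of the perturbed state (de-mixed
#'   sample or complex).
#' @param reference \linkS4class{PeakTable} of the dispersed/free state.
#' @param normRegion integer c(from, to); defaults to the C-terminal tail
#'   400-414, which stays sharp in all states.
#' @return data.frame residue_number, ratio, reverse (NA where a residue is
#'   missing from either table); attribute \code{normalization_region}.
#' @export
broadeningProfiles <- function(state, reference, normRegion = c(400, 414)) {
  ps <- state@peaks; pr <- reference@peaks
  normOf <- function(df) {
    sel <- df$residue_number >= normRegion[1] &
      df$residue_number <= normRegion[2]
    if (!any(sel)) stop("normalization region empty in a peak table")
    m <- median(df$intensity[sel])
    if (m == 0) stop("zero median intensity in normalization region")
    m
  }
  ns <- normOf(ps); nr <- normOf(pr)
  res <- sort(unique(c(ps$residue_number, pr$residue_number)))
  is_ <- match(res, ps$residue_number)
  ir <- match(res, pr$residue_number)
  ratio <- (ps$intensity[is_] / ns) / (pr$intensity[ir] / nr)
  out <- data.frame(residue_number = res, ratio = ratio,
                    reverse = pmax(1 - ratio, 0))
  attr(out, "normalization_region") <- normRegion
  out
}

#' 3J(HN-HA) coupling from HNHA cross/diagonal intensities
#'
#' Inverts the Vuister-Bax relation \eqn{I_{cross}/I_{diag} =
#' -\tan^2(2\pi J \zeta)} to \eqn{J =
#' \arctan(\sqrt{-ratio})/(2\pi\zeta)}.  Couplings near 4 Hz lean helical,
#' near 8 Hz beta-strand, and a cluster around 6 Hz is typical of a
#' disordered ensemble; classification thresholds are <= 5 Hz
#' (helix-leaning) and >= 7 Hz (strand-leaning).
#'
#' @param crossIntensity HNHA cross-peak intensities (opposite sign to the
#'   diagonal).
#' @param diagIntensity diagonal intensities (> 0).
#' @param zeta HNHA dephasing delay in seconds (default 13.05 ms).
#' @param residueNumber optional residue numbers for the output.
#' @return data.frame residue_number, J (Hz), class, implausible flag
#'   (J > 12 Hz).
#' @export
hnhaJcoupling <- function(crossIntensity, diagIntensity, zeta = 0.01305,
                          residueNumber = seq_along(crossIntensity)) {
  if (any(diagIntensity <= 0)) stop("diagonal intensity must be > 0")
  ratio <- crossIntensity / diagIntensity
  if (any(ratio > 0))
    stop("positive cross/diagonal ratio violates the HNHA sign convention")
  J <- atan(sqrt(-ratio)) / (2 * pi * zeta)
  cls <- ifelse(J <= 5, "helix-leaning", ifelse(J >= 7, "strand-leaning",
                                                "coil"))
  data.frame(residue_number = residueNumber, J = J, class = cls,
             implausible = J > 12)
}

#' Forward HNHA intensity ratio for a given coupling
#' @param J coupling in Hz.
#' @param zeta HNHA dephasing delay in seconds.
#' @return cross/diagonal intensity ratio (<= 0).
#' @export
hnhaForwardRatio <- function(J, zeta = 0.01305) -tan(2 * pi * J * zeta)^2
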