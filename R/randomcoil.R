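# Random-coil chemical-shift reference for intrinsically disordered
# proteins.  Base values follow the commonly tabulated random-coil shifts
# for short unstructured peptides at 25 C, near-neutral pH, referenced to
# DSS; neighbour corrections cover the dominant Gly/Pro context effects and
# per-atom temperature coefficients move the reference to the sample
# temperature.  A simple Henderson-Hasselbalch interpolation handles the
# Asp/Glu/His protonation shifts at acidic pH.

.rcRefTemperature <- 298.15
.rcRefPH <- 6.5

.rcBase <- local({
  ca <- c(A = 52.8, R = 56.5, N = 53.3, D = 54.2, C = 58.6, Q = 56.2,
          E = 56.9, G = 45.4, H = 55.6, I = 61.6, L = 55.5, K = 56.7,
          M = 55.8, F = 58.1, P = 63.5, S = 58.7, T = 62.0, V = 62.6,
          W = 57.6, Y = 58.3)
  cb <- c(A = 19.0, R = 30.6, N = 38.8, D = 41.0, C = 28.2, Q = 29.2,
          E = 30.0, G = NA, H = 29.6, I = 38.6, L = 42.2, K = 32.8,
          M = 32.9, F = 39.6, P = 32.0, S = 63.9, T = 69.7, V = 32.6,
          W = 29.5, Y = 38.9)
  n15 <- c(A = 125.0, R = 121.2, N = 119.0, D = 120.4, C = 118.7,
           Q = 119.8, E = 120.6, G = 109.1, H = 118.9, I = 120.6,
           L = 121.8, K = 121.3, M = 120.0, F = 120.1, P = NA, S = 116.0,
           T = 114.2, V = 119.9, W = 121.5, Y = 120.5)
  hn <- c(A = 8.24, R = 8.23, N = 8.40, D = 8.34, C = 8.32, Q = 8.32,
          E = 8.42, G = 8.33, H = 8.42, I = 8.00, L = 8.16, K = 8.25,
          M = 8.28, F = 8.30, P = NA, S = 8.31, T = 8.15, V = 8.03,
          W = 8.25, Y = 8.12)
  list(CA = ca, CB = cb, N = n15, H = hn)
})

# ppm per K, applied as coef * (T - Tref); amide observables carry the
# well-known negative temperature dependence, carbons are nearly inert
.rcTempCoef <- c(CA = -0.0005, CB = -0.0002, N = -0.0027, H = -0.0047)

# neighbour corrections added to residue i for a Pro at i+1 or a Gly at
# i-1/i+1 (the dominant sequence-context effects in disordered chains)
.rcNeighbour <- list(
  nextPro = c(CA = -1.9, CB = -0.1, N = -0.6, H = -0.1),
  nextGly = c(CA = 0.0, CB = 0.0, N = 0.4, H = 0.05),
  prevGly = c(CA = 0.1, CB = 0.0, N = 0.8, H = 0.1))

# protonated-minus-deprotonated shift differences for titrating residues
.rcProtDelta <- list(
  D = c(CA = -1.3, CB = -2.8, N = -0.6, H = 0.1, pKa = 3.9),
  E = c(CA = -0.5, CB = -1.7, N = -0.4, H = 0.1, pKa = 4.3),
  H = c(CA = -0.7, CB = -1.0, N = -1.5, H = 0.3, pKa = 6.5))

#' Neighbour-corrected random-coil chemical-shift reference
#'
#' Predicts Calpha, Cbeta, amide N and HN random-coil shifts for a
#' disordered chain, with corrections for Gly/Pro sequence context,
#' temperature (per-atom linear coefficients relative to 298.15 K) and
#' acidic-pH protonation of Asp/Glu/His.  Methionine-sulfoxide positions
#' use the unmodified Met coefficients (no random-coil table exists for
#' the modified residue); mask them downstream instead.
#'
#' @param record a \linkS4class{SequenceRecord}.
#' @param temperature sample temperature in K (clamped to 273-333 with a
#'   warning outside the calibrated range).
#' @param pH sample pH (clamped to 2-12).
#' @param atoms atom names to predict, subset of CA, CB, N, H.
#' @return A \linkS4class{ShiftTable} at the requested conditions.
#' @examples
#' ref <- randomCoilReference(tdp43Sequence("PLD309"), 288, 6.8)
#' head(shifts(ref))
#' @export
randomCoilReference <- function(record, temperature = 288, pH = 6.8,
                                atoms = c("CA", "CB", "N", "H")) {
  atoms <- match.arg(atoms, c("CA", "CB", "N", "H"), several.ok = TRUE)
  if (temperature < 273 || temperature > 333) {
    warning("temperature outside calibrated range; clamped")
    temperature <- min(max(temperature, 273), 333)
  }
  if (pH < 2 || pH > 12) {
    warning("pH outside calibrated range; clamped")
    pH <- min(max(pH, 2), 12)
  }
  s <- strsplit(seqString(record), "")[[1]]
  rn <- residueNumbers(record)
  n <- length(s)
  out <- list()
  for (atom in atoms) {
    val <- .rcBase[[atom]][s]
    # sequence-context corrections
    nxt <- c(s[-1], NA)
    prv <- c(NA, s[-n])
    val <- val + ifelse(!is.na(nxt) & nxt == "P",
                        .rcNeighbour$nextPro[atom], 0)
    val <- val + ifelse(!is.na(nxt) & nxt == "G",
                        .rcNeighbour$nextGly[atom], 0)
    val <- val + ifelse(!is.na(prv) & prv == "G",
                        .rcNeighbour$prevGly[atom], 0)
    # temperature
    val <- val + .rcTempCoef[atom] * (temperature - .rcRefTemperature)
    # protonation of titrating side chains (own-residue effect)
    for (res in names(.rcProtDelta)) {
      d <- .rcProtDelta[[res]]
      fProt <- 1 / (1 + 10^(pH - d["pKa"])) -
        1 / (1 + 10^(.rcRefPH - d["pKa"]))
      val[s == res] <- val[s == res] + unname(d[atom]) * fProt
    }
    keep <- !is.na(val)
    out[[atom]] <- data.frame(residue_number = rn[keep],
                              residue_type = AA3[s[keep]],
                              atom_name = atom, shift = unname(val[keep]),
                              oxidized = record@oxidized[keep])
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  ShiftTable(df, temperature = temperature, pH = pH,
             assumedConditions = FALSE)
}

#' Random-coil reference tables
#'
#' Exposes the base shift table, temperature coefficients (ppm/K) and the
#' reference conditions used by \code{\link{randomCoilReference}}.
#' @return list with elements \code{base}, \code{temperatureCoefficients},
#'   \code{referenceTemperature}, \code{referencePH}.
#' @export
randomCoilTables <- function()
  list(base = .rcBase, temperatureCoefficients = .rcTempCoef,
       referenceTemperature = .rcRefTemperature, referencePH = .rcRefPH)
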