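# Sequence-derived biophysical properties: molar extinction coefficient at
# 280 nm, isoelectric point by Henderson-Hasselbalch bisection, and
# Kyte-Doolittle hydrophobicity profiles.

# side-chain and terminal pKa sets; "expasy" follows the Bjellqvist
# convention used by common web calculators, "emboss" the EMBOSS iep one
.pkaSets <- list(
  expasy = c(Nterm = 7.5, Cterm = 3.55, D = 4.05, E = 4.45, H = 5.98,
             C = 9.0, Y = 10.0, K = 10.0, R = 12.0),
  emboss = c(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, H = 6.5,
             C = 8.5, Y = 10.1, K = 10.8, R = 12.5))

.kyteDoolittle <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Molar extinction coefficient at 280 nm
#'
#' \eqn{\epsilon_{280} = 5500 n_{Trp} + 1490 n_{Tyr} + 125 n_{cystine}}
#' (Gill-von Hippel / Pace convention).  Cysteines are counted as free
#' (reduced), i.e. the cystine term is zero, which reproduces the values
#' used for concentration determination of TDP-43 (44,920) and its
#' prion-like domain (17,990) in 1/(M cm).
#'
#' @param record a \linkS4class{SequenceRecord}.
#' @return extinction coefficient in 1/(M cm).
#' @examples
#' extinctionCoefficient(tdp43Sequence("PLD"))   # 17990
#' @export
extinctionCoefficient <- function(record) {
  s <- strsplit(seqString(record), "")[[1]]
  if (!length(s)) stop("empty sequence")
  5500 * sum(s == "W") + 1490 * sum(s == "Y")
}

#' Net charge of a sequence at given pH
#'
#' Henderson-Hasselbalch sum over D, E, C, Y side chains and the C-terminus
#' (acids) and H, K, R and the N-terminus (bases).
#'
#' @param record a \linkS4class{SequenceRecord}.
#' @param pH pH value(s).
#' @param pkaSet "expasy" (Bjellqvist, default) or "emboss".
#' @return net charge in elementary units, one value per pH.
#' @export
netCharge <- function(record, pH, pkaSet = c("expasy", "emboss")) {
  pka <- .pkaSets[[match.arg(pkaSet)]]
  s <- strsplit(seqString(record), "")[[1]]
  counts <- table(factor(s, levels = AA1))
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - pka["Nterm"])) +
      sum(vapply(c("H", "K", "R"), function(a)
        counts[a] / (1 + 10^(p - pka[a])), 0))
    neg <- 1 / (1 + 10^(pka["Cterm"] - p)) +
      sum(vapply(c("D", "E", "C", "Y"), function(a)
        counts[a] / (1 + 10^(pka[a] - p)), 0))
    unname(pos - neg)
  }, 0)
}

#' Isoelectric point
#'
#' Finds the pH of zero net charge by bisection of \code{\link{netCharge}}
#' to |charge| < 1e-4, and returns the net-charge curve on a pH 0-14 grid
#' (step 0.1) alongside.  The net-charge function is strictly decreasing in
#' pH, so the root is unique.
#'
#' @inheritParams netCharge
#' @return list with elements \code{pI} and \code{netChargeCurve}
#'   (data.frame pH, charge).
#' @examples
#' isoelectricPoint(tdp43Sequence("PLD"))$pI   # about 10.0
#' @export
isoelectricPoint <- function(record, pkaSet = c("expasy", "emboss")) {
  pkaSet <- match.arg(pkaSet)
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    q <- netCharge(record, mid, pkaSet)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  grid <- seq(0, 14, by = 0.1)
  list(pI = mid,
       netChargeCurve = data.frame(pH = grid,
                                   charge = netCharge(record, grid, pkaSet)))
}

#' Kyte-Doolittle hydrophobicity profile
#'
#' Sliding-window mean of the Kyte-Doolittle scale; at the termini the
#' window shrinks to the available residues.  Output is indexed in
#' full-protein numbering.
#'
#' @param record a \linkS4class{SequenceRecord}.
#' @param window odd window size >= 1 (default 7).
#' @return data.frame with columns residue_number, residue, score.
#' @export
hydrophobicityProfile <- function(record, window = 7) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be an odd integer >= 1")
  s <- strsplit(seqString(record), "")[[1]]
  v <- .kyteDoolittle[s]
  half <- (window - 1) / 2
  n <- length(v)
  score <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - half):min(n, i + half)]), 0)
  data.frame(residue_number = residueNumbers(record), residue = s,
             score = unname(score))
}
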