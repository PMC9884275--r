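# 15N relaxation analysis: monoexponential R1/R2 fitting with Monte-Carlo
# errors, heteronuclear NOE with noise propagation, and the rotational
# correlation time estimated from the R2/R1 ratio over a filtered residue
# subset.

# 15N/1H gyromagnetic ratio magnitude; converts a 1H field to the 15N
# Larmor frequency
.gammaRatioN <- 0.10136

.fitExpOnce <- function(delays, intensities, start) {
  df <- data.frame(t = delays, I = intensities)
  fit <- tryCatch(
    nls(I ~ A * exp(-R * t), data = df, start = start,
        control = list(maxiter = 100, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      minpack.lm::nlsLM(I ~ A * exp(-R * t), data = df, start = start),
      error = function(e) NULL)
  fit
}

#' Fit a monoexponential decay with Monte-Carlo errors
#'
#' Least-squares fit of \eqn{I(t) = A e^{-Rt}}.  The rate uncertainty is
#' the standard deviation of rates refit on \code{nMc} synthetic data sets
#' in which Gaussian noise of the series' \code{noiseSigma} is added to the
#' fitted curve.  Initialisation is a log-linear regression seed plus three
#' perturbed restarts (deterministic given \code{seed}).
#'
#' @param series a \linkS4class{DecaySeries}.
#' @param nMc number of Monte-Carlo refits (0 for point estimates only).
#' @param seed integer seed for the Monte-Carlo noise.
#' @return list with rate, rateError (NA when nMc = 0), amplitude, fitted
#'   values and residual standard deviation.
#' @examples
#' d <- DecaySeries(321, c(.02, .06, .15, .24, .46, .8, 1.6),
#'                  exp(-2 * c(.02, .06, .15, .24, .46, .8, 1.6)), 0.01)
#' fitMonoexponential(d, nMc = 50, seed = 1)$rate
#' @export
fitMonoexponential <- function(series, nMc = 500, seed = NULL) {
  t <- series@delays
  I <- series@intensities
  if (length(unique(I)) == 1L) stop("intensities are all equal")
  pos <- I > 0
  startR <- if (sum(pos) >= 2) {
    cf <- coef(lm(log(I[pos]) ~ t[pos]))
    max(-cf[2], 1e-3)
  } else 1
  startA <- max(I)
  starts <- list(list(A = startA, R = startR),
                 list(A = startA, R = startR * 2),
                 list(A = startA, R = startR / 2),
                 list(A = startA * 1.5, R = startR))
  best <- NULL
  for (st in starts) {
    fit <- .fitExpOnce(t, I, st)
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) best <- fit
  }
  if (is.null(best)) stop("exponential fit did not converge (",
                          length(starts), " starts)")
  cf <- coef(best)
  rateErr <- NA_real_
  if (nMc > 0) {
    if (!is.null(seed)) set.seed(seed)
    base <- cf["A"] * exp(-cf["R"] * t)
    rates <- vapply(seq_len(nMc), function(i) {
      Ii <- base + rnorm(length(t), 0, series@noiseSigma)
      f <- .fitExpOnce(t, Ii, list(A = cf["A"], R = cf["R"]))
      if (is.null(f)) NA_real_ else coef(f)["R"]
    }, 0)
    rateErr <- sd(rates, na.rm = TRUE)
  }
  list(rate = unname(cf["R"]), rateError = rateErr,
       amplitude = unname(cf["A"]),
       fitted = unname(cf["A"] * exp(-cf["R"] * t)),
       residualSd = sqrt(deviance(best) / max(1, length(t) - 2)))
}

#' Heteronuclear (1H)-15N NOE with error propagation
#'
#' NOE = I_sat / I_unsat per residue; the uncertainty is
#' \eqn{|NOE|\sqrt{(\sigma_{sat}/I_{sat})^2 +
#' (\sigma_{unsat}/I_{unsat})^2}} with each sigma the spectral noise of the
#' corresponding spectrum.  Residues with non-positive reference intensity
#' are skipped with a reason; negative saturated intensities pass through
#' as negative NOEs (expected at flexible termini).
#'
#' @param sat \linkS4class{PeakTable} with amide-proton saturation.
#' @param unsat \linkS4class{PeakTable} without saturation.
#' @return list with \code{noe} (data.frame residue_number, noe, error) and
#'   \code{skipped} (data.frame residue_number, reason).
#' @export
heteronuclearNoe <- function(sat, unsat) {
  ps <- sat@peaks; pu <- unsat@peaks
  res <- intersect(ps$residue_number, pu$residue_number)
  if (!length(res)) stop("no shared residues")
  is_ <- match(res, ps$residue_number)
  iu <- match(res, pu$residue_number)
  Is <- ps$intensity[is_]; Iu <- pu$intensity[iu]
  bad <- Iu <= 0
  noe <- Is[!bad] / Iu[!bad]
  err <- abs(noe) * sqrt((sat@noiseSigma / Is[!bad])^2 +
                           (unsat@noiseSigma / Iu[!bad])^2)
  list(noe = data.frame(residue_number = res[!bad], noe = noe, error = err),
       skipped = data.frame(residue_number = res[bad],
                            reason = rep("non-positive reference intensity",
                                         sum(bad))))
}

#' Residue subset filter for correlation-time estimation
#'
#' Excludes residues whose internal motion or exchange broadening would
#' bias the R2/R1 estimator: residue i is excluded iff
#' \eqn{T2_i < \bar{T2} - \sigma(T2)} unless
#' \eqn{T1_i > \bar{T1} + \sigma(T1)} (the rescue clause).  Means and
#' population standard deviations are computed over the full input set.
#'
#' @param rates data.frame with columns residue_number, R1, R2 (1/s).
#' @param sdType "population" (default) or "sample".
#' @return list with \code{included} (residue numbers) and \code{excluded}
#'   (data.frame residue_number, reason).
#' @export
taucSubsetFilter <- function(rates, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (nrow(rates) < 3) stop("need at least 3 residues")
  T1 <- 1 / rates$R1
  T2 <- 1 / rates$R2
  popSd <- function(v) {
    s <- sd(v)
    if (sdType == "population") s * sqrt((length(v) - 1) / length(v)) else s
  }
  lowT2 <- T2 < mean(T2) - popSd(T2)
  highT1 <- T1 > mean(T1) + popSd(T1)
  excl <- lowT2 & !highT1
  list(included = rates$residue_number[!excl],
       excluded = data.frame(residue_number = rates$residue_number[excl],
                             reason = rep("low T2", sum(excl))))
}

#' Rotational correlation time from the R2/R1 ratio
#'
#' \eqn{\tau_c \simeq \sqrt{6 R_2/R_1 - 7} / (4\pi\nu_N)} with
#' \eqn{\nu_N} the 15N Larmor frequency in Hz, evaluated on the mean rates
#' over the filtered residue subset.  The estimator discounts
#' high-frequency spectral-density terms, so it is meaningful only for
#' residues with little internal motion and no exchange broadening - hence
#' the subset filter.
#'
#' @param rates data.frame with columns residue_number, R1, R2 (1/s).
#' @param fieldMHz spectrometer 1H frequency in MHz.
#' @param applyFilter apply \code{\link{taucSubsetFilter}} first (default).
#' @param average "rates" averages R1 and R2 before forming the ratio
#'   (default); "times" averages T1 and T2.
#' @param gammaRatio 15N/1H gyromagnetic-ratio magnitude (default 0.10136).
#' @return list with tauc (s), taucNs, meanR1, meanR2, nu_N (Hz),
#'   includedResidues and excluded (data.frame).
#' @examples
#' r <- data.frame(residue_number = 1:4, R1 = 1.5, R2 = 3.0)
#' estimateTauc(r, 600)$taucNs   # about 2.93
#' @export
estimateTauc <- function(rates, fieldMHz, applyFilter = TRUE,
                         average = c("rates", "times"),
                         gammaRatio = .gammaRatioN) {
  average <- match.arg(average)
  flt <- if (applyFilter) taucSubsetFilter(rates) else
    list(included = rates$residue_number,
         excluded = data.frame(residue_number = integer(),
                               reason = character()))
  sub <- rates[rates$residue_number %in% flt$included, , drop = FALSE]
  if (average == "rates") {
    mR1 <- mean(sub$R1); mR2 <- mean(sub$R2)
  } else {
    mR1 <- 1 / mean(1 / sub$R1); mR2 <- 1 / mean(1 / sub$R2)
  }
  ratio <- mR2 / mR1
  nuN <- fieldMHz * 1e6 * gammaRatio
  radicand <- 6 * ratio - 7
  if (radicand < 0)
    stop("undefined correlation time: mean R2/R1 below 7/6 ",
         "(protein too flexible for this estimator)")
  tauc <- sqrt(radicand) / (4 * pi * nuN)
  list(tauc = tauc, taucNs = tauc * 1e9, meanR1 = mR1, meanR2 = mR2,
       nu_N = nuN, includedResidues = flt$included,
       excluded = flt$excluded)
}
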