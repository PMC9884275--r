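# Plate-reader statistics: turbidity area-under-curve for phase-separation
# quantification, sigmoidal thioflavin-T aggregation fits, and CD
# mean-residue-weight ellipticity conversion.

#' Area under a turbidity curve
#'
#' Trapezoidal integral of A600 over [0, tEnd] hours as the standard
#' phase-separation readout.  With several replicate traces the traces are
#' averaged point-wise first (they must share a time grid) and the
#' standard deviation across per-replicate AUCs is reported.
#'
#' @param traces a \linkS4class{KineticTrace} or list of replicates.
#' @param tEnd integration end in hours (default 24); traces must cover
#'   it, no extrapolation is performed.
#' @param baselineSubtract subtract the t = 0 signal first (default
#'   FALSE, raw A600).
#' @return list with auc (of the replicate-average trace), sd (across
#'   replicate AUCs, NA for a single trace), perReplicate.
#' @examples
#' tr <- KineticTrace(seq(0, 24, 0.25), rep(0.2, 97))
#' turbidityAuc(tr)$auc   # 4.8
#' @export
turbidityAuc <- function(traces, tEnd = 24, baselineSubtract = FALSE) {
  if (is(traces, "KineticTrace")) traces <- list(traces)
  aucOne <- function(tr) {
    tt <- tr@time
    y <- tr@signal
    if (baselineSubtract) y <- y - y[1]
    if (max(tt) < tEnd)
      stop(sprintf("trace ends at %.2f h, before tEnd = %g h", max(tt),
                   tEnd))
    keep <- tt <= tEnd
    tt2 <- tt[keep]; y2 <- y[keep]
    if (max(tt2) < tEnd) {           # interpolate the exact end point
      yEnd <- stats::approx(tt, y, xout = tEnd)$y
      tt2 <- c(tt2, tEnd); y2 <- c(y2, yEnd)
    }
    pracma::trapz(tt2, y2)
  }
  per <- vapply(traces, aucOne, 0)
  grid <- traces[[1]]@time
  same <- all(vapply(traces, function(tr)
    length(tr@time) == length(grid) && all(tr@time == grid), TRUE))
  if (!same) stop("replicate traces must share one time grid")
  avg <- rowMeans(vapply(traces, function(tr) tr@signal,
                         numeric(length(grid))))
  avgTrace <- KineticTrace(grid, avg, replicateId = "mean",
                           condition = traces[[1]]@condition,
                           kind = traces[[1]]@kind)
  list(auc = aucOne(avgTrace),
       sd = if (length(per) > 1) sd(per) else NA_real_,
       perReplicate = per)
}

.logistic <- function(t, y0, A, k, tHalf) y0 + A / (1 + exp(-k * (t - tHalf)))

.fitLogisticOnce <- function(tt, y) {
  y0s <- min(y); As <- max(y) - min(y)
  tHalfS <- tt[which.min(abs(y - (y0s + As / 2)))]
  span <- diff(range(tt))
  ks <- 4 / max(span / 4, 1e-6)
  df <- data.frame(t = tt, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A / (1 + exp(-k * (t - tHalf))), data = df,
                      start = list(y0 = y0s, A = As, k = ks,
                                   tHalf = tHalfS),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("sigmoid fit did not converge")
  fit
}

#' Fit sigmoidal aggregation kinetics
#'
#' Fits the symmetric logistic \eqn{y(t) = y_0 + A/(1 + e^{-k(t -
#' t_{1/2})})} to each replicate ThT trace.  With >= 2 replicates the
#' reported \eqn{t_{1/2}} is the mean across replicate fits with its
#' standard deviation; with a single replicate the SD comes from the fit
#' covariance.
#'
#' @param traces a \linkS4class{KineticTrace} or list of replicates.
#' @return list with tHalf (h), tHalfSd, k (1/h), y0, A, residualRms,
#'   extrapolated flag (tHalf outside the observed time range),
#'   perReplicate data.frame.
#' @export
fitSigmoidKinetics <- function(traces) {
  if (is(traces, "KineticTrace")) traces <- list(traces)
  fits <- lapply(traces, function(tr) {
    if (length(tr@time) < 5) stop("need >= 5 points per trace")
    rng <- range(tr@signal)
    if (diff(rng) <= 0) stop("flat trace: no transition to fit")
    if (cor(tr@time, tr@signal) < -0.5)
      stop("monotone-decreasing signal; baseline correction needed?")
    .fitLogisticOnce(tr@time, tr@signal)
  })
  cfs <- t(vapply(fits, coef, c(y0 = 0, A = 0, k = 0, tHalf = 0)))
  per <- data.frame(replicate = vapply(traces, function(tr)
    tr@replicateId, ""), cfs)
  tHalf <- mean(cfs[, "tHalf"])
  tHalfSd <- if (nrow(cfs) > 1) sd(cfs[, "tHalf"]) else {
    se <- tryCatch(summary(fits[[1]])$coefficients["tHalf", "Std. Error"],
                   error = function(e) NA_real_)
    se
  }
  rms <- sqrt(mean(unlist(lapply(fits, residuals))^2))
  tmin <- min(vapply(traces, function(tr) min(tr@time), 0))
  tmax <- max(vapply(traces, function(tr) max(tr@time), 0))
  list(tHalf = tHalf, tHalfSd = tHalfSd, k = mean(cfs[, "k"]),
       y0 = mean(cfs[, "y0"]), A = mean(cfs[, "A"]), residualRms = rms,
       extrapolated = tHalf < tmin || tHalf > tmax, perReplicate = per)
}

#' Mean-residue-weight ellipticity
#'
#' Converts a raw CD signal to \eqn{\Theta_{mrw} = \theta \cdot
#' MRW/(10 \cdot l \cdot c)} in deg cm^2/dmol, with \eqn{\theta} in
#' millidegrees, pathlength l in cm, concentration c in mg/ml and MRW the
#' mean residue molecular weight (default 98 g/mol).
#'
#' @param theta ellipticity in millidegrees.
#' @param conc protein concentration in mg/ml.
#' @param path cuvette pathlength in cm.
#' @param mrw mean residue weight in g/mol.
#' @return mean-residue-weight ellipticity, deg cm^2/dmol.
#' @export
mrwEllipticity <- function(theta, conc, path, mrw = 98) {
  if (conc <= 0 || path <= 0) stop("conc and path must be > 0")
  theta * mrw / (10 * path * conc)
}

#' @importFrom stats approx cor residuals
NULL
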