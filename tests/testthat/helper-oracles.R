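# Independent oracles used across the suite.

# Horn's quaternion method for the minimal pairwise RMSD between two
# centred coordinate sets; independent of the SVD-based rotation in the
# package.
quaternionRmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  S <- t(P) %*% Q
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3],
    S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1],
    S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3],
    S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2],
    -S[1, 1] - S[2, 2] + S[3, 3]), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ssq <- sum(P^2) + sum(Q^2) - 2 * lambda
  sqrt(max(ssq, 0) / nrow(P))
}

# apply a random rigid-body transform to an n x 3 coordinate matrix
randomRigid <- function(X) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(X %*% Q, 2, runif(3, -10, 10), `+`)
}

# quick two-peak-table builder
peakTab <- function(res, h, n, I, sigma = 0.01)
  PeakTable(data.frame(residue_number = res, h_ppm = h, n_ppm = n,
                       intensity = I), noiseSigma = sigma)
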