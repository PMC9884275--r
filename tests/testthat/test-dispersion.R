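test_that("R2eff conversion from constant-time intensities", {
  expect_equal(r2effFromIntensities(1, 1, 0.06)$r2eff, 0)
  expect_equal(r2effFromIntensities(0.5, 1, 0.06)$r2eff, log(2) / 0.06,
               tolerance = 1e-12)
  expect_equal(r2effFromIntensities(exp(-1), 1, 1)$r2eff, 1)
  up <- r2effFromIntensities(1.2, 1, 0.06)
  expect_true(up$flagged)
  expect_error(r2effFromIntensities(-1, 1, 0.06))
})

test_that("exchange models collapse correctly in their limits", {
  nu <- defaultCpmgFields()
  for (mdl in c("luz-meiboom", "carver-richards")) {
    # no shift difference: flat at R2_0 (evaluated in the dw -> 0 limit)
    flat <- dispersionModelEval(mdl, list(kex = 2000, pB = 0.05,
                                          dwPpm = 1e-9, r20 = 8), nu, 800)
    expect_equal(flat, rep(8, length(nu)), tolerance = 1e-6)
    # full refocusing at very high field
    hi <- dispersionModelEval(mdl, list(kex = 2000, pB = 0.05, dwPpm = 2,
                                        r20 = 8), 1e6, 800)
    expect_equal(hi, 8, tolerance = 1e-4)
  }
  expect_error(dispersionModelEval("luz-meiboom",
                                   list(kex = -1, pB = 0.05, dwPpm = 1,
                                        r20 = 8), nu), "invalid")
})

test_that("the Luz-Meiboom zero-frequency limit equals the full Rex", {
  kex <- 3000; pB <- 0.04; dw <- 2; r20 <- 8; field <- 800
  r0 <- dispersionModelEval("luz-meiboom",
                            list(kex = kex, pB = pB, dwPpm = dw,
                                 r20 = r20), 0, field)
  dwRad <- 2 * pi * dw * field * 0.10136
  expect_equal(r0 - r20, (1 - pB) * pB * dwRad^2 / kex, tolerance = 1e-9)
})

test_that("closed forms agree with the Bloch-McConnell propagator", {
  nu <- defaultCpmgFields()
  worstCR <- 0
  worstLM <- 0
  for (kex in c(500, 1500, 5000))
    for (pB in c(0.01, 0.05, 0.2))
      for (dw in c(0.5, 1.5, 3)) {
        bm <- blochMcConnellR2eff(nu, kex, pB, dw, 8, 800, 0.06)
        cr <- dispersionModelEval("carver-richards",
                                  list(kex = kex, pB = pB, dwPpm = dw,
                                       r20 = 8), nu, 800)
        worstCR <- max(worstCR, max(abs(cr - bm) / bm))
        dwRad <- 2 * pi * dw * 800 * 0.10136
        if (kex / dwRad > 4) {        # fast-exchange regime only
          lm <- dispersionModelEval("luz-meiboom",
                                    list(kex = kex, pB = pB, dwPpm = dw,
                                         r20 = 8), nu, 800)
          worstLM <- max(worstLM, max(abs(lm - bm) / bm))
        }
      }
  expect_lt(worstCR, 0.01)
  expect_lt(worstLM, 0.01)
})

test_that("the dispersion amplitude statistic is a plain RMSD", {
  expect_equal(r2Rmsd(c(10, 12), c(10, 12)), 0)
  expect_equal(r2Rmsd(c(10, 12), c(11, 11)), 1.0)
  expect_equal(r2Rmsd(5, 3), 2)
  expect_equal(r2Rmsd(c(10, 12), 11), 1.0)   # scalar average recycles
  expect_error(r2Rmsd(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("flat curves select the no-exchange model", {
  cv <- genDispersionCurves(3000, 0.05, c(`1` = 0, `2` = 0), r20 = 8,
                            sigma = 0.1, seed = 2)
  f <- fitDispersion(cv, model = "auto", nMc = 0, nRestarts = 3,
                     seed = 2)
  expect_equal(f$model, "none")
  expect_true(is.na(f$kex))
  expect_equal(f$perResidue$r20, c(8, 8), tolerance = 0.2)
})

test_that("point fits without Monte-Carlo report undefined errors", {
  cv <- genDispersionCurves(3000, 0.05, c(`321` = 2), sigma = 0.3,
                            seed = 4)
  f <- fitDispersion(cv, model = "carver-richards", nMc = 0,
                     nRestarts = 3, seed = 4)
  expect_true(is.na(f$kexError))
  expect_true(all(is.na(f$kexCI95)))
  expect_false(f$kexLowerBound)
  expect_gt(f$kex, 0)
})

test_that("fits are deterministic for a fixed seed", {
  cv <- genDispersionCurves(3000, 0.05, c(`321` = 2, `323` = 1.5),
                            sigma = 0.3, seed = 8)
  f1 <- fitDispersion(cv, model = "luz-meiboom", nMc = 10, nRestarts = 3,
                      seed = 9)
  f2 <- fitDispersion(cv, model = "luz-meiboom", nMc = 10, nRestarts = 3,
                      seed = 9)
  expect_identical(f1$kex, f2$kex)
  expect_identical(f1$kexError, f2$kexError)
})

test_that("exchange parameters are recovered across seeded datasets", {
  errs <- vapply(1:20, function(s) {
    cv <- genDispersionCurves(3000, 0.05, c(`1` = 2, `2` = 2.5),
                              r20 = 8, sigma = 0.3, seed = 100 + s)
    f <- fitDispersion(cv, model = "carver-richards", nMc = 0,
                       nRestarts = 4, seed = 100 + s)
    abs(f$kex - 3000) / 3000
  }, 0)
  expect_lt(median(errs), 0.15)
})
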