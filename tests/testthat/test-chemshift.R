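test_that("random-coil reference reproduces base-table entries exactly", {
  tab <- randomCoilTables()
  # every residue in an Ala-flanked context (no Gly/Pro corrections) at
  # the tables' reference conditions must hit the base value exactly
  aa <- names(tab$base$CA)
  for (x in setdiff(aa, "A")) {
    rec <- SequenceRecord(paste0("A", x, "A"))
    ref <- randomCoilReference(rec, tab$referenceTemperature,
                               tab$referencePH)
    df <- shifts(ref)
    mid <- df[df$residue_number == 2, ]
    for (atom in c("CA", "CB", "N", "H")) {
      base <- tab$base[[atom]][x]
      if (is.na(base)) next
      if (x %in% c("D", "E", "H")) next  # titrating side chains shift
      expect_equal(mid$shift[mid$atom_name == atom], unname(base),
                   info = paste(x, atom))
    }
  }
})

test_that("temperature correction is linear with the shipped coefficients", {
  tab <- randomCoilTables()
  rec <- SequenceRecord("AAA")
  r1 <- shifts(randomCoilReference(rec, 288, 6.5))
  r2 <- shifts(randomCoilReference(rec, 308, 6.5))
  for (atom in c("CA", "N", "H")) {
    d <- r2$shift[r2$atom_name == atom][1] -
      r1$shift[r1$atom_name == atom][1]
    expect_equal(d, unname(tab$temperatureCoefficients[atom] * 20),
                 tolerance = 1e-10, info = atom)
  }
  expect_warning(randomCoilReference(rec, 400, 7), "clamped")
})

test_that("the PLD reference covers every residue's Calpha", {
  pld <- tdp43Sequence("PLD")
  ref <- shifts(randomCoilReference(pld, 288, 6.8))
  ca <- ref[ref$atom_name == "CA", ]
  expect_equal(sort(ca$residue_number), 274:414)
})

test_that("secondary shifts difference observed minus reference", {
  rec <- tdp43Sequence("PLD309")
  ref <- randomCoilReference(rec, 288, 6.8, atoms = c("CA", "CB"))
  prof0 <- secondaryShifts(ref, ref)
  expect_true(all(abs(prof0$d_ca) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(prof0$d_ca_cb) < 1e-12, na.rm = TRUE))

  # a +3.1 ppm Calpha offset with untouched Cbeta is the 100%-helix mark
  obs <- shifts(ref)
  obs$shift[obs$atom_name == "CA"] <- obs$shift[obs$atom_name == "CA"] + 3.1
  prof <- secondaryShifts(ShiftTable(obs), ref)
  expect_equal(prof$d_ca_cb[!is.na(prof$d_ca_cb)],
               rep(3.1, sum(!is.na(prof$d_ca_cb))))

  other <- ShiftTable(data.frame(residue_number = 1, residue_type = "ALA",
                                 atom_name = "CA", shift = 52.8))
  expect_error(secondaryShifts(other, ref), "shared")
})

test_that("planted helical blocks are recovered with Met masking honoured", {
  rec <- tdp43Sequence("PLD309", oxidized = TRUE)
  st <- genShiftDataset(rec, c(324, 332), 0.8, seed = 7, sigma = 0.02)
  ref <- randomCoilReference(rec, 288, 6.8, atoms = c("CA", "CB"))
  prof <- secondaryShifts(st, ref, maskOxidizedMet = TRUE)
  expect_false(any(prof$residue_number %in% oxidizedPositions(rec)))
  inside <- prof$d_ca[prof$residue_number >= 324 &
                        prof$residue_number <= 332]
  outside <- prof$d_ca[prof$residue_number < 324 |
                         prof$residue_number > 332]
  expect_true(all(inside > 2.3, na.rm = TRUE))
  expect_true(all(abs(outside) < 0.1, na.rm = TRUE))
})

test_that("helical population scales, clamps and validates", {
  prof <- data.frame(residue_number = 324:332, d_ca = 3.1, d_cb = 0,
                     d_ca_cb = 3.1)
  expect_equal(helicalPopulation(prof, c(324, 332))$population, 1)
  prof$d_ca <- 0
  expect_equal(helicalPopulation(prof, c(324, 332))$population, 0)
  # linear in a uniform offset until clamping
  for (f in c(0.1, 0.27, 0.8)) {
    prof$d_ca <- 3.1 * f
    expect_equal(helicalPopulation(prof, c(324, 332))$population, f,
                 tolerance = 1e-12)
  }
  prof$d_ca <- 6.2
  expect_equal(helicalPopulation(prof, c(324, 332))$population, 1)
  expect_error(helicalPopulation(prof, c(500, 510)), "empty")
})

test_that("chemical-shift perturbation follows the weighted formula", {
  a <- peakTab(1:3, c(8.0, 8.1, 8.2), c(120, 121, 122), 1)
  expect_true(all(chemicalShiftPerturbation(a, a)$csp == 0))
  b <- peakTab(1:3, c(8.0, 8.1, 8.2) + c(0.10, 0, 0.03),
               c(120, 121, 122) + c(0.50, 0, 0.10), 1)
  csp <- chemicalShiftPerturbation(a, b)
  expect_equal(csp$csp[1], sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_equal(csp$csp[2], 0)
  # unit 15N scaling reduces to the Euclidean distance
  eucl <- chemicalShiftPerturbation(a, b, nScale = 1)
  expect_equal(eucl$csp[1], sqrt(0.10^2 + 0.50^2), tolerance = 1e-12)
  # missing residues are NA, not zero
  c3 <- peakTab(2:4, c(8.1, 8.2, 8.3), c(121, 122, 123), 1)
  m <- chemicalShiftPerturbation(a, c3)
  expect_true(is.na(m$csp[m$residue_number == 1]))
  expect_true(is.na(m$csp[m$residue_number == 4]))
  expect_error(chemicalShiftPerturbation(a, peakTab(9, 8, 120, 1)),
               "shared")
})

test_that("CSP is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  tabs <- lapply(1:3, function(i)
    peakTab(1:6, 8 + rnorm(6, 0, 0.1), 120 + rnorm(6, 0, 1), 1))
  ab <- chemicalShiftPerturbation(tabs[[1]], tabs[[2]])$csp
  ba <- chemicalShiftPerturbation(tabs[[2]], tabs[[1]])$csp
  bc <- chemicalShiftPerturbation(tabs[[2]], tabs[[3]])$csp
  ac <- chemicalShiftPerturbation(tabs[[1]], tabs[[3]])$csp
  expect_equal(ab, ba)
  expect_true(all(ac <= ab + bc + 1e-12))
})

test_that("broadening profiles normalise, ratio and reverse correctly", {
  res <- 300:414
  ref <- peakTab(res, 8, 120, rep(100, length(res)))
  same <- broadeningProfiles(ref, ref)
  expect_true(all(same$ratio == 1))
  expect_true(all(same$reverse == 0))

  I <- rep(100, length(res))
  I[res >= 305 & res <= 345] <- 50
  state <- peakTab(res, 8, 120, I)
  bp <- broadeningProfiles(state, ref, normRegion = c(400, 414))
  expect_equal(bp$reverse[bp$residue_number == 320], 0.5)
  expect_equal(bp$reverse[bp$residue_number == 380], 0)

  # a missing residue is reported missing
  state2 <- peakTab(res[res != 320], 8, 120, I[res != 320])
  bp2 <- broadeningProfiles(state2, ref)
  expect_true(is.na(bp2$ratio[bp2$residue_number == 320]))

  zero <- peakTab(res, 8, 120, rep(0, length(res)))
  expect_error(broadeningProfiles(zero, ref), "zero median")
})

test_that("HNHA couplings invert the Vuister-Bax relation", {
  expect_equal(hnhaJcoupling(0, 1)$J, 0)
  expect_equal(hnhaJcoupling(0, 1)$class, "helix-leaning")
  j6 <- hnhaJcoupling(-0.2857, 1, zeta = 0.01305)
  expect_equal(j6$J, 6.0, tolerance = 5e-3)
  expect_equal(j6$class, "coil")
  # classes at the 4 / 8 Hz anchors
  r48 <- hnhaForwardRatio(c(4, 8))
  cls <- hnhaJcoupling(r48, c(1, 1))$class
  expect_equal(cls, c("helix-leaning", "strand-leaning"))
  expect_error(hnhaJcoupling(0.5, 1), "sign convention")
  expect_error(hnhaJcoupling(-0.5, 0), "diagonal")
  # inversion is the identity over the invertible branch
  zeta <- 0.01305
  Js <- seq(0, 1 / (4 * zeta) * 0.99 / 2, length.out = 40)
  back <- hnhaJcoupling(hnhaForwardRatio(Js, zeta), rep(1, 40),
                        zeta = zeta)$J
  expect_equal(back, Js, tolerance = 1e-9)
  expect_true(hnhaJcoupling(hnhaForwardRatio(12.5, zeta), 1,
                            zeta = zeta)$implausible)
})
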