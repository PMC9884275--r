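test_that("FASTA reading handles headers, offsets and bad residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFG", ">b offset=10", "MNPQ"), f)
  recs <- readFasta(f)
  expect_length(recs, 2)
  expect_equal(nchar(seqString(recs$a)), 6)
  expect_equal(residueNumbers(recs$b), 10:13)

  pld <- tdp43Sequence("PLD")
  rn <- residueNumbers(pld)
  expect_equal(rn[1], 274)
  expect_equal(rn[length(rn)], 414)
  expect_equal(nchar(seqString(pld)), 141)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACBDE"), bad)
  expect_error(readFasta(bad), "position 3")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(readFasta(empty))
})

test_that("FASTA round-trips including oxidation flags", {
  rec <- SequenceRecord("GAMmAG", id = "ox", offset = 300L)
  expect_equal(oxidizedPositions(rec), 303)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(rec, f)
  back <- readFasta(f)[[1]]
  expect_equal(seqString(back), seqString(rec))
  expect_equal(back@oxidized, rec@oxidized)
  expect_equal(back@offset, rec@offset)
})

test_that("NMR-STAR shift loops parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_test", "loop_", "  _Atom_chem_shift.Seq_ID",
               "  _Atom_chem_shift.Comp_ID", "  _Atom_chem_shift.Atom_ID",
               "  _Atom_chem_shift.Val",
               "  324 ALA CA 52.9", "  324 ALA CB 19.1",
               "  325 MSO CA 55.1", "stop_"), f)
  st <- readNmrStarShifts(f)
  expect_s4_class(st, "ShiftTable")
  expect_equal(nrow(shifts(st)), 3)
  expect_true(st@assumedConditions)
  expect_equal(unname(conditions(st)), c(288, 6.8))
  # sulfoxide comp id normalised to MET + flag
  ox <- shifts(st)[shifts(st)$residue_number == 325, ]
  expect_equal(ox$residue_type, "MET")
  expect_true(ox$oxidized)

  dup <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_d", "loop_", "  _Atom_chem_shift.Seq_ID",
               "  _Atom_chem_shift.Comp_ID", "  _Atom_chem_shift.Atom_ID",
               "  _Atom_chem_shift.Val", "  1 GLY CA 45.1",
               "  1 GLY CA 45.2", "stop_"), dup)
  expect_error(readNmrStarShifts(dup), "duplicate")

  noloop <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_e", "# nothing"), noloop)
  expect_error(readNmrStarShifts(noloop), "format error")

  out <- withr::local_tempfile(fileext = ".str")
  writeNmrStarShifts(st, out)
  back <- readNmrStarShifts(out)
  expect_false(back@assumedConditions)
  expect_equal(shifts(back)$shift, shifts(st)$shift, tolerance = 1e-4)
  expect_equal(shifts(back)$oxidized, shifts(st)$oxidized)
})

test_that("Sparky lists parse residue numbers and flag negatives", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c(" Assignment  w1  w2  Data Height",
               "M323N-H 121.5 8.10 150000",
               "A324N-H 124.9 8.22 -2000",
               "S332N-H 116.1 8.35 98000"), f)
  pt <- readSparkyList(f, noiseSigma = 500)
  expect_equal(nrow(peaks(pt)), 3)
  expect_equal(residueNumbers(pt), c(323, 324, 332))
  expect_true(peaks(pt)$flagged[peaks(pt)$residue_number == 324])
  expect_equal(peaks(pt)$h_ppm[1], 8.10)

  bad <- withr::local_tempfile(fileext = ".list")
  writeLines(c("M323N-H 121.5 8.10 1", "garbage 1 2 3"), bad)
  expect_error(readSparkyList(bad, 1), "line 2")

  out <- withr::local_tempfile(fileext = ".list")
  writeSparkyList(pt, out)
  back <- readSparkyList(out, noiseSigma = 500)
  expect_equal(peaks(back)$intensity, peaks(pt)$intensity,
               tolerance = 1e-6)
  expect_equal(residueNumbers(back), residueNumbers(pt))
})

test_that("multi-model PDB ensembles read, validate and round-trip", {
  e <- genToyEnsemble(2, 4, 0.3, seed = 1, startResidue = 324,
                      atomNames = c("N", "CA", "C", "O"))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeModelEnsemble(e, f)
  back <- readModelEnsemble(f)
  expect_equal(nConformers(back), 2)
  expect_equal(atomRoster(back)$atom_name, atomRoster(e)$atom_name)
  expect_equal(coords(back), coords(e), tolerance = 1e-3)

  single <- genToyEnsemble(1, 4, 0, seed = 1)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeModelEnsemble(single, f1)
  expect_equal(nConformers(readModelEnsemble(f1)), 1)

  # differing rosters across MODEL blocks must be rejected
  mism <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       3.800   0.000   0.000  1.00  0.00",
    "ENDMDL", "END"), mism)
  expect_error(readModelEnsemble(mism), "roster")
})

test_that("mmCIF atom_site loops parse into ensembles", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_toy", "loop_", "_atom_site.group_PDB",
               "_atom_site.label_atom_id", "_atom_site.label_comp_id",
               "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
               "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.pdbx_PDB_model_num",
               "ATOM CA ALA 1 0.0 0.0 0.0 1",
               "ATOM CA ALA 2 3.8 0.0 0.0 1",
               "ATOM CA ALA 1 0.1 0.0 0.0 2",
               "ATOM CA ALA 2 3.9 0.0 0.0 2"), f)
  e <- readModelEnsemble(f)
  expect_equal(nConformers(e), 2)
  expect_equal(residueNumbers(e), c(1, 2))
  expect_equal(coords(e)[2, 1, 2], 3.9)
})

test_that("time-series tables validate shape and monotonicity", {
  f <- withr::local_tempfile(fileext = ".csv")
  tt <- seq(0, 96, by = 0.25)
  write.csv(data.frame(time_h = tt, r1 = tt * 0.01, r2 = tt * 0.02), f,
            row.names = FALSE)
  st <- readSeriesTable(f, xUnit = "h")
  expect_equal(length(st@x), 385)   # 96 h at 15-min steps
  expect_equal(names(st@columns), c("r1", "r2"))

  one <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_h = 1:3), one, row.names = FALSE)
  expect_error(readSeriesTable(one), "no trace columns")

  nonmono <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_h = c(1, 3, 2), y = 1:3), nonmono,
            row.names = FALSE)
  expect_error(readSeriesTable(nonmono), "increasing")

  out <- withr::local_tempfile(fileext = ".csv")
  writeSeriesTable(st, out)
  back <- readSeriesTable(out, xUnit = "h")
  expect_equal(back@x, st@x)
  expect_equal(back@columns, st@columns)
})
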