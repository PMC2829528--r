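test_that("reading a minimal PDB echoes its CA coordinates", {
  f <- threeResidueFixture()
  s <- readStructure(f)
  expect_s4_class(s, "CaStructure")
  expect_equal(length(s), 3L)
  expect_equal(caCoords(s),
               matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(residueNames(s), c("ALA", "GLY", "SER"))
})

test_that("selecting an absent chain errors with 'no CA atoms'", {
  f <- threeResidueFixture()
  expect_error(readStructure(f, chain = "B"), "no CA atoms")
  expect_error(readStructure(paste0(f, ":B")), "no CA atoms")
  s <- readStructure(paste0(f, ":A"))
  expect_equal(length(s), 3L)
  expect_match(structureId(s), ":A$")
})

test_that("altloc duplicates collapse to a single residue", {
  f <- writePdbFixture(c(
    pdbCaLine(1, "ALA", "A", 1, c(0, 0, 0), alt = "A"),
    pdbCaLine(2, "ALA", "A", 1, c(9, 9, 9), alt = "B"),
    pdbCaLine(3, "GLY", "A", 2, c(3.8, 0, 0))))
  s <- readStructure(f)
  expect_equal(length(s), 2L)
  expect_equal(caCoords(s)[1, ], c(0, 0, 0))   # altloc A kept, B dropped
})

test_that("MSE maps to MET and unknown residues are skipped with a warning", {
  f <- writePdbFixture(c(
    pdbCaLine(1, "ALA", "A", 1, c(0, 0, 0)),
    pdbCaLine(2, "MSE", "A", 2, c(3.8, 0, 0), type = "HETATM"),
    pdbCaLine(3, "XYZ", "A", 3, c(7.6, 0, 0))))
  expect_warning(s <- readStructure(f), "XYZ")
  expect_equal(residueNames(s), c("ALA", "MET"))
})

test_that("only the first model of a multi-model file is read", {
  f <- writePdbFixture(c(
    "MODEL        1",
    pdbCaLine(1, "ALA", "A", 1, c(0, 0, 0)),
    pdbCaLine(2, "GLY", "A", 2, c(3.8, 0, 0)),
    "ENDMDL",
    "MODEL        2",
    pdbCaLine(3, "ALA", "A", 1, c(1, 0, 0)),
    pdbCaLine(4, "GLY", "A", 2, c(4.8, 0, 0)),
    "ENDMDL"))
  s <- suppressWarnings(readStructure(f))
  expect_equal(length(s), 2L)
  expect_equal(caCoords(s)[1, ], c(0, 0, 0))
})

test_that("missing files error", {
  expect_error(readStructure("/no/such/file.pdb"), "not found")
})

test_that("read-write-read round trip preserves geometry to PDB precision", {
  set.seed(51)
  s <- randomBackbone(25, seed = 9)
  f <- tempfile(fileext = ".pdb")
  writeTransformedPdb(s, identityTransform(), f)
  s2 <- readStructure(f)
  expect_equal(length(s2), length(s))
  expect_equal(residueNames(s2), residueNames(s))
  expect_lt(max(abs(caCoords(s2) - caCoords(s))), 0.001 + 1e-9)
})

test_that("written coordinates follow the (H - t) R convention", {
  s <- caStructure(matrix(c(1, 0, 0), 1, 3), resid = "ALA")
  f <- tempfile(fileext = ".pdb")
  # pure translation moves (1,0,0) to the origin
  writeTransformedPdb(s, rigidTransform(diag(3), c(1, 0, 0)), f)
  expect_equal(caCoords(readStructure(f))[1, ], c(0, 0, 0))
  # 90 degree rotation about z after zero translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  writeTransformedPdb(s, rigidTransform(Rz, c(0, 0, 0)), f)
  xyz <- caCoords(readStructure(f))[1, ]
  expect_equal(xyz[1], 0, tolerance = 1e-9)
  expect_equal(abs(xyz[2]), 1, tolerance = 1e-9)
})

test_that("PIR output has equal-width gapped rows and round-trips", {
  fam <- makeFamily(familySpec(templateLength = 20, K = 3, indelRate = 0.06,
                               seed = 12))
  res <- mapsci(fam$structures)
  f <- tempfile(fileext = ".pir")
  writePir(res, f)
  entries <- readPir(f)
  expect_equal(length(entries), 4L)   # consensus + 3 proteins
  expect_equal(length(unique(nchar(entries))), 1L)
  # gap patterns agree with the correspondence
  idx <- correspondenceMatrix(res)
  for (j in 1:3) {
    want <- is.na(idx[j + 1, ])
    got <- strsplit(entries[[j + 1]], "")[[1]] == "-"
    expect_identical(got, want)
  }
  # round trip: writing the parsed gap pattern again changes nothing
  f2 <- tempfile(fileext = ".pir")
  writePir(res, f2)
  expect_identical(readPir(f2), entries)
})

test_that("consensus pseudo-structure is written as UNK records", {
  fam <- makeFamily(familySpec(templateLength = 12, K = 2, seed = 13))
  res <- mapsci(fam$structures)
  f <- tempfile(fileext = ".pdb")
  writeConsensusPdb(res, f)
  txt <- readLines(f)
  expect_true(any(grepl("UNK", txt)))
  expect_equal(sum(grepl("^ATOM", txt)), nrow(consensusCoords(res)))
})

test_that("exportAlignment writes the full output set", {
  fam <- makeFamily(familySpec(templateLength = 15, K = 2, seed = 14))
  res <- mapsci(fam$structures)
  dir <- tempfile()
  rep <- exportAlignment(res, dir)
  expect_true(file.exists(file.path(dir, "consensus.pdb")))
  expect_true(file.exists(file.path(dir, "alignment.pir")))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_equal(length(list.files(dir, pattern = "_aligned\\.pdb$")), 2L)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$core_size, rep$core_size)
})
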