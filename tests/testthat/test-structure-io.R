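oneAtom <- "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C"

test_that("single coordinate records parse field by field", {
  s <- readPDBStructure(c(oneAtom, "END"))
  at <- atoms(s)
  expect_equal(nrow(at), 1L)
  expect_equal(at$record, "ATOM")
  expect_equal(at$serial, 1L)
  expect_equal(at$name, "CA")
  expect_equal(at$resname, "ALA")
  expect_equal(at$chain, "A")
  expect_equal(at$resno, 1L)
  expect_equal(at$x, 11.104)
  expect_equal(at$element, "C")

  h <- readPDBStructure(
    "HETATM    5  O   HOH B 201       5.000   5.000   5.000  1.00  0.00           O")
  expect_equal(atoms(h)$record, "HETATM")
  expect_equal(atoms(h)$resname, "HOH")
})

test_that("only the first MODEL of a multi-model file is kept", {
  txt <- c("MODEL        1", oneAtom, "ENDMDL", "MODEL        2",
           sub("11\\.104", "99.000", oneAtom), "ENDMDL", "END")
  s <- readPDBStructure(txt)
  expect_equal(nrow(atoms(s)), 1L)
  expect_equal(atoms(s)$x, 11.104)
})

test_that("elements are inferred from atom names when columns 77-78 are blank", {
  bare <- substr(oneAtom, 1, 54)
  s <- readPDBStructure(c(bare, "END"))
  expect_equal(atoms(s)$element, "C")
  zn <- "HETATM    2 ZN    ZN B 101       0.000   0.000   0.000  1.00  0.00"
  expect_equal(atoms(readPDBStructure(zn))$element, "ZN")
})

test_that("unparseable records and empty files are errors with position", {
  bad <- c(oneAtom, sub("6\\.134", "6.1q4 ", oneAtom), "END")
  expect_error(readPDBStructure(bad), "line 2")
  expect_error(readPDBStructure(c("HEADER    TEST", "END")),
               "zero atoms")
  expect_error(readPDBStructure(c("ATOM      1  CA", "END")),
               "line 1.*short")
})

test_that("MODRES and LINK records are captured", {
  txt <- c("MODRES 1ABC MSE A    2  MET  SELENOMETHIONINE",
           "LINK         SG  CYS A   2                ZN    ZN B 101",
           oneAtom, "END")
  s <- readPDBStructure(txt)
  expect_equal(s@modres$resname, "MSE")
  expect_equal(s@modres$chain, "A")
  expect_equal(s@modres$resno, 2L)
  expect_equal(s@links$name1, "SG")
  expect_equal(s@links$chain2, "B")
  expect_equal(s@links$resno2, 101L)
})

altlocPdb <- c(
  "ATOM      1  CA AALA A   1      11.639   6.071  -5.147  0.60  0.00           C",
  "ATOM      2  CA BALA A   1      11.700   6.100  -5.200  0.40  0.00           C",
  "ATOM      3  CB  ALA A   1      12.000   6.500  -5.500  1.00  0.00           C",
  "END")

test_that("altloc selection keeps the dominant conformer", {
  s <- selectAltloc(readPDBStructure(altlocPdb))
  at <- atoms(s)
  expect_equal(nrow(at), 2L)                  # CA once, CB untouched
  expect_equal(at$altloc[at$name == "CA"], "A")
  expect_equal(at$occupancy[at$name == "CA"], 0.6)

  # occupancy tie resolves to the alphabetically smallest altloc
  tie <- sub("0\\.60", "0.50", sub("0\\.40", "0.50", altlocPdb))
  st <- selectAltloc(readPDBStructure(tie))
  expect_equal(atoms(st)$altloc[atoms(st)$name == "CA"], "A")

  # identity on altloc-free structures, and post-selection uniqueness
  plain <- readPDBStructure(c(oneAtom, "END"))
  expect_identical(atoms(selectAltloc(plain)), atoms(plain))
  key <- with(atoms(s), paste(chain, resno, icode, name))
  expect_false(any(duplicated(key)))
})

test_that("write/parse round-trips at 3-decimal precision", {
  for (f in list(fixtureSuite()$ligand_rules, randomFixture(30, 7))) {
    s1 <- f$structure
    s2 <- readPDBStructure(writePDBStructure(s1))
    a1 <- atoms(s1); a2 <- atoms(s2)
    expect_equal(nrow(a1), nrow(a2))
    for (col in c("record", "name", "resname", "chain", "resno", "icode"))
      expect_equal(a2[[col]], a1[[col]])
    for (col in c("x", "y", "z"))
      expect_equal(a2[[col]], a1[[col]], tolerance = 1e-3)
    expect_equal(nrow(s2@modres), nrow(s1@modres))
    expect_equal(nrow(s2@links), nrow(s1@links))
  }
})

test_that("coordinates beyond the fixed-column field refuse to write", {
  s <- readPDBStructure(c(oneAtom, "END"))
  s@atoms$x <- 123456.0
  expect_error(writePDBStructure(s), "fixed-column")
})
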