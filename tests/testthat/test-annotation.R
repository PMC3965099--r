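mkRegions <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(pdb_id = r[["pdb_id"]] %||% "XXXX", chain = "A",
               start = as.integer(r[["start"]]), start_icode = "",
               end = as.integer(r[["end"]]), end_icode = "",
               pfam_acc = r[["acc"]], pfam_id = tolower(r[["acc"]]),
               e_value = as.numeric(r[["e"]]), stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("regions on obsolete entries are dropped, order preserved", {
  reg <- rbind(mkRegions(list(start = 1, end = 10, acc = "PF1", e = 1)),
               mkRegions(list(start = 1, end = 10, acc = "PF2", e = 1)))
  reg$pdb_id <- c("1SC5", "9XYZ")
  expect_equal(filterObsolete(reg, "1SC5")$pdb_id, "1SC5")
  expect_equal(nrow(filterObsolete(reg, character(0))), 0L)
  expect_equal(filterObsolete(reg, c("1SC5", "9XYZ")), reg)
})

test_that("overlapping matches keep only the most significant E-value", {
  reg <- mkRegions(list(start = 10, end = 100, acc = "PF00001", e = 1e-10),
                   list(start = 50, end = 120, acc = "PF00002", e = 1e-5))
  out <- resolveOverlaps(reg)
  expect_equal(out$pfam_acc, "PF00001")

  disjoint <- mkRegions(list(start = 10, end = 100, acc = "PF00001", e = 1e-10),
                        list(start = 101, end = 150, acc = "PF00002", e = 1e-5))
  expect_equal(sort(resolveOverlaps(disjoint)$pfam_acc),
               c("PF00001", "PF00002"))

  three <- mkRegions(list(start = 10, end = 60, acc = "PF00001", e = 1e-20),
                     list(start = 40, end = 90, acc = "PF00002", e = 1e-10),
                     list(start = 55, end = 70, acc = "PF00003", e = 1e-5))
  expect_equal(resolveOverlaps(three)$pfam_acc, "PF00001")
})

test_that("E-value ties break by length then accession", {
  tie <- mkRegions(list(start = 10, end = 50, acc = "PF00009", e = 1e-5),
                   list(start = 10, end = 80, acc = "PF00005", e = 1e-5))
  expect_equal(resolveOverlaps(tie)$pfam_acc, "PF00005")   # longer
  tie2 <- mkRegions(list(start = 10, end = 50, acc = "PF00009", e = 1e-5),
                    list(start = 10, end = 50, acc = "PF00005", e = 1e-5))
  expect_equal(resolveOverlaps(tie2)$pfam_acc, "PF00005")  # lexicographic
})

test_that("resolution matches the brute-force subset oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:30) {
    reg <- randomRegions(sample(2:8, 1L))
    out <- resolveOverlaps(reg)
    expect_true(noOverlaps(out))
    expect_equal(resolveOverlaps(out), out)
    oracle <- bruteForceResolve(reg)
    expect_setequal(out$pfam_acc, oracle$pfam_acc)
    # every discarded region overlaps a kept, more significant one
    lost <- reg[!reg$pfam_acc %in% out$pfam_acc, , drop = FALSE]
    for (i in seq_len(nrow(lost))) {
      clash <- out$end >= lost$start[i] & lost$end[i] >= out$start
      expect_true(any(clash & out$e_value <= lost$e_value[i]))
    }
  }
})

test_that("a curated E-value of zero always wins overlap resolution", {
  reg <- mkRegions(list(start = 10, end = 100, acc = "PF00001", e = 0),
                   list(start = 50, end = 120, acc = "PF00002", e = 1e-30))
  expect_equal(resolveOverlaps(reg)$pfam_acc, "PF00001")
  tsv <- "XXXX\tA\t10\t.\t100\t.\tPF00001\tfam\t0"
  expect_equal(readDomainRegions(tsv)$e_value, 0)
})

fiveRes <- readPDBStructure(vapply(1:5, function(i) sprintf(
  "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
  i, i, i * 20.0, 0, 0), character(1)))

test_that("domain regions resolve to their residue ranges", {
  reg <- mkRegions(list(start = 1, end = 3, acc = "PF00240", e = 1e-10))
  inst <- attachDomains(fiveRes, reg)
  expect_length(inst, 1L)
  expect_equal(inst[[1L]]@residueKeys, c("A|1|", "A|2|", "A|3|"))

  regZ <- reg; regZ$chain <- "Z"
  expect_warning(instZ <- attachDomains(fiveRes, regZ), "absent")
  expect_length(instZ, 0L)

  # two copies of one family on different chains stay distinct
  two <- readPDBStructure(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY B   1      50.000   0.000   0.000  1.00  0.00           C"))
  regAB <- rbind(mkRegions(list(start = 1, end = 1, acc = "PF00240", e = 1e-10)),
                 mkRegions(list(start = 1, end = 1, acc = "PF00240", e = 1e-10)))
  regAB$chain <- c("A", "B")
  instAB <- attachDomains(two, regAB)
  expect_length(instAB, 2L)
  expect_equal(vapply(instAB, function(d) d@region$pfam_acc, ""),
               rep("PF00240", 2L))
})

test_that("ligand identification applies all four exclusion rules", {
  f <- fixtureSuite()$ligand_rules
  ligs <- identifyLigands(f$structure)
  expect_equal(vapply(ligs, function(l) l@hetCode, ""), "ZN")

  # solvent and nucleic exclusions are extensible
  s <- f$structure
  expect_length(identifyLigands(s, solventExtra = "ZN"), 0L)

  # ATOM-record residues are never ligands
  r <- randomFixture(10, 3)$structure
  expect_length(identifyLigands(r), 0L)
})
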