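writeFixtureInputs <- function(f, dir) {
  pdb <- file.path(dir, "fixture.pdb")
  dom <- file.path(dir, "domains.tsv")
  writeLines(f$pdb, pdb)
  writeLines(f$domains, dom)
  c(pdb = pdb, domains = dom)
}

test_that("the pipeline writes four consistent, byte-deterministic tables", {
  f <- fixtureSuite()$hyd_ddi_inter
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  res <- suppressWarnings(runPipeline(paste(f$pdb, collapse = "\n"),
                                      paste(f$domains, collapse = "\n"),
                                      outDir = out1))
  expect_true(all(file.exists(res$files)))
  it <- read.delim(res$files[["interactions"]])
  expect_equal(nrow(it), 1L)
  bonds <- read.delim(res$files[["bonds"]])
  expect_equal(bonds$bond_type, "hydrogen")      # the vdw bond is flag-only
  rc <- read.delim(res$files[["residue_contacts"]])
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$vdw_flag, 1L)
  expect_true(all(bonds$interaction_id %in% it$interaction_id))

  suppressWarnings(runPipeline(paste(f$pdb, collapse = "\n"),
                               paste(f$domains, collapse = "\n"),
                               outDir = out2))
  for (nm in basename(res$files))
    expect_identical(readBin(file.path(out1, nm), "raw", 1e6),
                     readBin(file.path(out2, nm), "raw", 1e6))
})

test_that("structures without annotated domains exit cleanly with empty outputs", {
  dir <- withr::local_tempdir()
  f <- fixtureSuite()$vdw_ddi_inter
  paths <- writeFixtureInputs(f, dir)
  # annotations target a chain the structure lacks
  writeLines("XXXX\tZ\t1\t.\t1\t.\tPF00001\tDomA\t1e-10",
             paths[["domains"]])
  out <- file.path(dir, "empty")
  status <- suppressWarnings(cliMain(c("run", "--pdb", paths[["pdb"]],
                                       "--domains", paths[["domains"]],
                                       "--out", out)))
  expect_equal(status, 0L)
  it <- read.delim(file.path(out, "interactions.tsv"))
  expect_equal(nrow(it), 0L)
  expect_length(readLines(file.path(out, "interactions.tsv")), 1L)
})

test_that("missing inputs exit with status 2", {
  dir <- withr::local_tempdir()
  f <- fixtureSuite()$vdw_ddi_inter
  paths <- writeFixtureInputs(f, dir)
  expect_equal(cliMain(c("run", "--pdb", paths[["pdb"]],
                         "--domains", file.path(dir, "nope.tsv"),
                         "--out", file.path(dir, "x"))), 2L)
  expect_equal(cliMain(c("run", "--pdb", paths[["pdb"]],
                         "--out", file.path(dir, "x"))), 2L)
})

test_that("criteria overrides reach the bond rules from the command line", {
  dir <- withr::local_tempdir()
  f <- fixtureSuite()$vdw_ddi_inter          # single vdw contact at 4.15 A
  paths <- writeFixtureInputs(f, dir)
  out <- file.path(dir, "narrow")
  status <- cliMain(c("run", "--pdb", paths[["pdb"]],
                      "--domains", paths[["domains"]],
                      "--vdw-margin", "0.5", "--out", out))
  expect_equal(status, 0L)
  # 4.15 A lies beyond vdwsum + 0.5, so the interaction disappears
  expect_equal(nrow(read.delim(file.path(out, "interactions.tsv"))), 0L)
})
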