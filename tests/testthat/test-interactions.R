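runFixture <- function(f, ...) {
  suppressWarnings(runPipeline(paste(f$pdb, collapse = "\n"),
                               paste(f$domains, collapse = "\n"), ...))
}

test_that("an interaction needs at least one bond, and one suffices", {
  fx <- fixtureSuite()
  # two domains far out of every window: no call
  far <- buildFixture(
    data.frame(chain = c("A", "B"), resno = 1L, icode = "",
               resname = "ALA", atom = "CB", element = "C",
               x = c(0, 30), y = 0, z = 0, record = "ATOM",
               stringsAsFactors = FALSE),
    regions = data.frame(chain = c("A", "B"), start = 1L, end = 1L,
                         acc = c("PF00001", "PF00002"),
                         id = c("a", "b"), e_value = 1e-10))
  res <- runFixture(far)
  expect_length(res$interactions, 0L)

  # a single vdw bond between chains is a full intermolecular DDI
  res2 <- runFixture(fx$vdw_ddi_inter)
  expect_length(res2$interactions, 1L)
  x <- res2$interactions[[1L]]
  expect_equal(x@kind, "DDI")
  expect_equal(x@topology, "intermolecular")
  expect_equal(nrow(x@bonds), 0L)               # vdw never stored atom-wise
  expect_true(all(x@residueContacts$vdw_flag))
})

test_that("homodomain and topology are independent axes", {
  fx <- fixtureSuite()
  inter <- runFixture(fx$homo_ddi_inter)$interactions[[1L]]
  expect_equal(inter@relation, "homodomain")
  expect_equal(inter@topology, "intermolecular")
  intra <- runFixture(fx$homo_ddi_intra)$interactions[[1L]]
  expect_equal(intra@relation, "homodomain")
  expect_equal(intra@topology, "intramolecular")
})

test_that("a domain and a metal ion in the electrostatic window form a DLI", {
  res <- runFixture(fixtureSuite()$elec_dli_intra)
  expect_length(res$interactions, 1L)
  x <- res$interactions[[1L]]
  expect_equal(x@kind, "DLI")
  expect_equal(x@partnerB@hetCode, "ZN")
  expect_equal(x@nBondsByType[["electrostatic"]], 1L)
  expect_true(is.na(x@relation))
})

test_that("sequence-adjacent residues on one chain never provide evidence", {
  res <- runFixture(fixtureSuite()$adjacent_backbone)
  expect_length(res$interactions, 0L)
})

mkBond <- function(resa, resb, type, serial_a = 1L, serial_b = 2L) {
  data.frame(serial_a = serial_a, name_a = "X", resname_a = "ALA",
             chain_a = "A", resno_a = resa, icode_a = "",
             serial_b = serial_b, name_b = "Y", resname_b = "ALA",
             chain_b = "B", resno_b = resb, icode_b = "",
             bond_type = type, distance = 3.0, hbond_angle = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("residue aggregation collapses vdw to flags and keeps higher-order bonds", {
  bonds <- rbind(
    do.call(rbind, lapply(1:7, function(i) mkBond(40L, 12L, "vdw",
                                                  i, 100L + i))),
    mkBond(40L, 12L, "hydrogen", 8L, 108L))
  rc <- aggregateResidueContacts(bonds)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$n_higher_order, 1L)
  expect_true(rc$vdw_flag)
  expect_equal(rc$most_significant_bond, "hydrogen")
  expect_equal(rc$bond_types_present, "hydrogen,vdw")

  three <- rbind(mkBond(1L, 1L, "vdw"), mkBond(2L, 5L, "covalent"),
                 mkBond(3L, 9L, "electrostatic"))
  expect_equal(nrow(aggregateResidueContacts(three)), 3L)

  onlyV <- mkBond(1L, 1L, "vdw")
  rcv <- aggregateResidueContacts(onlyV)
  expect_equal(rcv$n_higher_order, 0L)
  expect_equal(rcv$most_significant_bond, "vdw")
})

test_that("aggregation conserves every non-vdw bond", {
  for (s in c(2, 9)) {
    f <- randomFixture(40, s)
    at <- atoms(f$structure)
    bonds <- suppressWarnings(
      detectBonds(at[at$chain == "A", ], at[at$chain == "B", ]))
    rc <- aggregateResidueContacts(bonds)
    expect_equal(sum(rc$n_higher_order), sum(bonds$bond_type != "vdw"))
    expect_equal(sum(rc$vdw_flag > 0),
                 length(unique(paste(bonds$resno_a, bonds$resno_b)[
                   bonds$bond_type == "vdw"])))
  }
})

test_that("the summary grid counts every interaction exactly once", {
  expect_true(all(summarizeInteractions(list()) == 0L))
  fx <- fixtureSuite()
  res <- runFixture(fx$homo_ddi_inter)
  sm <- summarizeInteractions(res$interactions)
  expect_equal(sm["intermolecular", "homodomain"], 1L)
  expect_equal(sum(sm), 1L)
  res2 <- runFixture(fx$elec_dli_intra)
  expect_equal(summarizeInteractions(res2$interactions)[
    "intramolecular", "ligand"], 1L)
  for (s in c(4, 21)) {
    r <- runFixture(randomFixture(25, s))
    expect_equal(sum(summarizeInteractions(r$interactions)),
                 length(r$interactions))
  }
})

test_that("the interaction set is invariant under partner order", {
  f <- fixtureSuite()$synthetic_sh3_sh2
  res <- runFixture(f)
  st <- res$structure
  doms <- res$domains
  fwd <- callInteractions(st, doms, list())
  rev <- callInteractions(st, rev(doms), list())
  expect_equal(length(fwd), length(rev))
  expect_equal(inventoryFromResult(list(interactions = fwd)),
               inventoryFromResult(list(interactions = rev)))
})

test_that("interface residues report the dominant bond class per position", {
  res <- runFixture(fixtureSuite()$synthetic_sh3_sh2)
  ir <- interfaceResidues(res$interactions[[1L]])
  expect_equal(sum(ir$side == "A"), 4L)   # PF00017 side
  expect_equal(sum(ir$side == "B"), 5L)   # PF00018 side
  expect_true(all(ir$most_significant_bond == "vdw"))
})
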