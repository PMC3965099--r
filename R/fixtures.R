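#' Build a synthetic structure with engineered bond geometry
#'
#' Assembles a parseable legacy-PDB structure plus a matching
#' domain-region TSV from explicit atom placements, validating that
#' every engineered contact's distance lies strictly inside its target
#' classification window under the shipped parameter table.  A contact
#' placed at (or outside) a window boundary is rejected, since the
#' strict-inequality rules make boundary placements ambiguous.
#'
#' @param placements data.frame with columns chain, resno, icode,
#'   resname, atom, element, x, y, z and optionally record (default
#'   "ATOM").
#' @param contacts optional data.frame with columns a, b (row indices
#'   into `placements`) and type (target bond class); used only for
#'   window validation.
#' @param regions data.frame with columns chain, start, end, acc, id,
#'   e_value (and optionally start_icode, end_icode).
#' @param pdbId four-character identifier for the emitted records.
#' @param modres optional data.frame (chain, resno, icode, resname).
#' @param links optional data.frame in the LINK layout of
#'   [PDBStructure-class].
#' @param jitter standard deviation (Angstrom) of seeded Gaussian noise
#'   added to atoms not referenced by any engineered contact.
#' @param seed integer seed for the jitter.
#' @return List with `structure` (a [PDBStructure-class]), `pdb`
#'   (character lines), `domains` (TSV lines) and `regions`.
#' @export
buildFixture <- function(placements, contacts = NULL, regions = NULL,
                         pdbId = "XXXX", modres = NULL, links = NULL,
                         jitter = 0, seed = 1L) {
  pl <- placements
  if (is.null(pl$record)) pl$record <- "ATOM"
  if (is.null(pl$icode)) pl$icode <- ""
  if (jitter > 0) {
    inContact <- seq_len(nrow(pl)) %in% c(contacts$a, contacts$b)
    old <- globalenv()$.Random.seed
    set.seed(seed)
    n <- sum(!inContact)
    pl$x[!inContact] <- pl$x[!inContact] + stats::rnorm(n, 0, jitter)
    pl$y[!inContact] <- pl$y[!inContact] + stats::rnorm(n, 0, jitter)
    pl$z[!inContact] <- pl$z[!inContact] + stats::rnorm(n, 0, jitter)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  atoms <- data.frame(record = pl$record, serial = seq_len(nrow(pl)),
                      name = pl$atom, altloc = "", resname = pl$resname,
                      chain = pl$chain, resno = as.integer(pl$resno),
                      icode = pl$icode, x = pl$x, y = pl$y, z = pl$z,
                      occupancy = 1, element = toupper(pl$element),
                      stringsAsFactors = FALSE)
  emptyMr <- data.frame(chain = character(0), resno = integer(0),
                        icode = character(0), resname = character(0),
                        stringsAsFactors = FALSE)
  if (!is.null(modres)) {
    if (is.null(modres$icode)) modres$icode <- ""
    modres$resno <- as.integer(modres$resno)
  }
  lkCols <- c("name1", "resname1", "chain1", "resno1", "icode1",
              "name2", "resname2", "chain2", "resno2", "icode2")
  emptyLk <- stats::setNames(
    data.frame(character(0), character(0), character(0), integer(0),
               character(0), character(0), character(0), character(0),
               integer(0), character(0), stringsAsFactors = FALSE), lkCols)
  if (!is.null(links)) {
    for (ic in c("icode1", "icode2"))
      if (is.null(links[[ic]])) links[[ic]] <- ""
    links$resno1 <- as.integer(links$resno1)
    links$resno2 <- as.integer(links$resno2)
    links <- links[, lkCols]
  }
  structure <- new("PDBStructure", pdbId = pdbId, atoms = atoms,
                   modres = if (is.null(modres)) emptyMr else modres,
                   links = if (is.null(links)) emptyLk else links)
  if (!is.null(contacts)) validateContacts(atoms, contacts)
  domains <- if (is.null(regions)) character(0) else
    regionTsv(regions, pdbId)
  list(structure = structure, pdb = writePDBStructure(structure),
       domains = domains, regions = regions)
}

validateContacts <- function(atoms, contacts, eps = 1e-6) {
  params <- defaultParams()
  crit <- bondCriteria()
  for (i in seq_len(nrow(contacts))) {
    ia <- contacts$a[i]; ib <- contacts$b[i]
    type <- contacts$type[i]
    ca <- chemLookup(params, atoms$resname[ia], atoms$name[ia],
                     atoms$element[ia])
    cb <- chemLookup(params, atoms$resname[ib], atoms$name[ib],
                     atoms$element[ib])
    if (is.na(ca$covalent_radius) || is.na(cb$covalent_radius))
      stop("engineered contact references an unparameterized atom")
    d <- sqrt(sum((unlist(atoms[ia, c("x", "y", "z")]) -
                   unlist(atoms[ib, c("x", "y", "z")]))^2))
    covsum <- ca$covalent_radius + cb$covalent_radius
    vdwsum <- ca$vdw_radius + cb$vdw_radius
    win <- switch(type,
                  covalent = c(0, covsum),
                  electrostatic = c(covsum, vdwsum),
                  hydrogen = c(covsum, crit@hbondMaxDist),
                  vdw = c(vdwsum, vdwsum + crit@vdwMargin),
                  stop("unknown engineered bond type: ", type))
    if (d <= win[1L] + eps || d >= win[2L] - eps)
      stop(sprintf(
        "engineered %s contact %d-%d at d=%.3f not strictly inside window (%.3f, %.3f)",
        type, ia, ib, d, win[1L], win[2L]))
  }
  invisible(TRUE)
}

regionTsv <- function(regions, pdbId) {
  ic <- function(v) if (is.null(v)) "." else ifelse(nzchar(v), v, ".")
  sprintf("%s\t%s\t%d\t%s\t%d\t%s\t%s\t%s\t%g",
          pdbId, regions$chain, as.integer(regions$start),
          ic(regions$start_icode), as.integer(regions$end),
          ic(regions$end_icode), regions$acc, regions$id,
          regions$e_value)
}

#' Seeded random two-chain fixture
#'
#' Two molecules of `n` single-atom residues each (chains A and B,
#' elements drawn from C/N/O/S), placed uniformly in a 20 Angstrom box,
#' with a domain annotation covering each chain.  Reproducible for a
#' fixed seed; used to compare grid-indexed against exhaustive bond
#' detection.
#'
#' @param n atoms per side (>= 1).
#' @param seed integer seed.
#' @return List with `structure`, `pdb`, `domains` as in
#'   [buildFixture()].
#' @export
randomFixture <- function(n, seed) {
  stopifnot(n >= 1L)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "S"), 2L * n, replace = TRUE)
  xyz <- matrix(stats::runif(6L * n, 0, 20), ncol = 3L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  pl <- data.frame(chain = rep(c("A", "B"), each = n),
                   resno = rep(seq_len(n), 2L), icode = "",
                   resname = "UNK", atom = elements, element = elements,
                   x = round(xyz[, 1L], 3L), y = round(xyz[, 2L], 3L),
                   z = round(xyz[, 3L], 3L), record = "ATOM",
                   stringsAsFactors = FALSE)
  regions <- data.frame(chain = c("A", "B"), start = 1L, end = n,
                        acc = c("PF00001", "PF00002"),
                        id = c("RndA", "RndB"), e_value = 1e-10,
                        stringsAsFactors = FALSE)
  buildFixture(pl, regions = regions, pdbId = "RND1")
}

#' The canonical engineered-fixture suite
#'
#' A named list of fixtures covering every bond class crossed with
#' DDI/DLI and intra-/inter-chain topology, the homodomain relation on
#' both topologies, the adjacent-domain backbone exclusion, all four
#' ligand-exclusion branches (solvent, nucleic acid, MODRES, same-chain
#' LINK) with a bridging-metal positive control, and a synthetic
#' stand-in for a minimal all-van-der-Waals two-domain interface (five
#' residues against four, no higher-order bonds).  Each fixture carries
#' the expected interaction inventory derived from its constructed
#' geometry, against which the full pipeline can be checked end to end.
#'
#' @return Named list; each element has `pdb`, `domains`,
#'   `expected` (data.frame of interaction rows) and `expectedLigands`.
#' @export
fixtureSuite <- function() {
  p <- function(chain, resno, resname, atom, element, x, y, z,
                record = "ATOM")
    data.frame(chain = chain, resno = resno, icode = "",
               resname = resname, atom = atom, element = element,
               x = x, y = y, z = z, record = record,
               stringsAsFactors = FALSE)
  reg <- function(chain, start, end, acc, id, e = 1e-10)
    data.frame(chain = chain, start = start, end = end, acc = acc,
               id = id, e_value = e, stringsAsFactors = FALSE)
  exp_row <- function(kind, fa, fb, topo, rel, ncov = 0L, nel = 0L,
                      nhy = 0L, nvdw = 0L, ncontacts) {
    data.frame(kind = kind, family_a = fa, family_b_or_het = fb,
               topology = topo, relation = rel, n_covalent = ncov,
               n_electrostatic = nel, n_hydrogen = nhy,
               n_residue_pairs_vdw = nvdw, n_contacts = ncontacts,
               stringsAsFactors = FALSE)
  }
  noInteractions <- exp_row("DDI", "x", "x", "x", "x",
                            ncontacts = 0L)[0L, ]
  fx <- list()

  # --- DDI, one fixture per bond class, interchain ---
  fx$cov_ddi_inter <- c(buildFixture(
    rbind(p("A", 1, "CYS", "SG", "S", 0, 0, 0),
          p("B", 1, "CYS", "SG", "S", 1.05, 0, 0)),
    contacts = data.frame(a = 1L, b = 2L, type = "covalent"),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("B", 1, 1, "PF00002", "DomB"))),
    list(expected = exp_row("DDI", "PF00001", "PF00002",
                            "intermolecular", "heterodomain", ncov = 1L,
                            ncontacts = 1L),
         expectedLigands = character(0)))

  fx$elec_ddi_inter <- c(buildFixture(
    rbind(p("A", 1, "LYS", "NZ", "N", 0, 0, 0),
          p("B", 1, "GLU", "OE1", "O", 2.22, 0, 0)),
    contacts = data.frame(a = 1L, b = 2L, type = "electrostatic"),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("B", 1, 1, "PF00002", "DomB"))),
    list(expected = exp_row("DDI", "PF00001", "PF00002",
                            "intermolecular", "heterodomain", nel = 1L,
                            ncontacts = 1L),
         expectedLigands = character(0)))

  # donor N against backbone C=O; the 120-degree acceptor angle puts
  # the donor 3.77 A from the antecedent carbon, which is a legitimate
  # van der Waals contact of the same residue pair (flagged, not stored
  # as a bond)
  hydGeom <- function(chainA, resA, chainB, resB)
    rbind(p(chainA, resA, "ALA", "N", "N", -1.5, 2.5981, 0),
          p(chainB, resB, "ALA", "C", "C", 1.23, 0, 0),
          p(chainB, resB, "ALA", "O", "O", 0, 0, 0))
  fx$hyd_ddi_inter <- c(buildFixture(
    hydGeom("A", 1, "B", 1),
    contacts = data.frame(a = c(1L, 1L), b = c(3L, 2L),
                          type = c("hydrogen", "vdw")),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("B", 1, 1, "PF00002", "DomB"))),
    list(expected = exp_row("DDI", "PF00001", "PF00002",
                            "intermolecular", "heterodomain", nhy = 1L,
                            nvdw = 1L, ncontacts = 1L),
         expectedLigands = character(0)))

  fx$vdw_ddi_inter <- c(buildFixture(
    rbind(p("A", 1, "ALA", "CB", "C", 0, 0, 0),
          p("B", 1, "ALA", "CB", "C", 4.15, 0, 0)),
    contacts = data.frame(a = 1L, b = 2L, type = "vdw"),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("B", 1, 1, "PF00002", "DomB"))),
    list(expected = exp_row("DDI", "PF00001", "PF00002",
                            "intermolecular", "heterodomain", nvdw = 1L,
                            ncontacts = 1L),
         expectedLigands = character(0)))

  # --- same four classes, both domains on one chain ---
  fx$cov_ddi_intra <- c(buildFixture(
    rbind(p("A", 1, "CYS", "SG", "S", 0, 0, 0),
          p("A", 10, "CYS", "SG", "S", 1.05, 0, 0)),
    contacts = data.frame(a = 1L, b = 2L, type = "covalent"),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("A", 10, 10, "PF00002", "DomB"))),
    list(expected = exp_row("DDI", "PF00001", "PF00002",
                            "intramolecular", "heterodomain", ncov = 1L,
                            ncontacts = 1L),
         expectedLigands = character(0)))

  fx$elec_ddi_intra <- c(buildFixture(
    rbind(p("A", 1, "LYS", "NZ", "N", 0, 0, 0),
          p("A", 10, "GLU", "OE1", "O", 2.22, 0, 0)),
    contacts = data.frame(a = 1L, b = 2L, type = "electrostatic"),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("A", 10, 10, "PF00002", "DomB"))),
    list(expected = exp_row("DDI", "PF00001", "PF00002",
                            "intramolecular", "heterodomain", nel = 1L,
                            ncontacts = 1L),
         expectedLigands = character(0)))

  fx$hyd_ddi_intra <- c(buildFixture(
    hydGeom("A", 1, "A", 10),
    contacts = data.frame(a = c(1L, 1L), b = c(3L, 2L),
                          type = c("hydrogen", "vdw")),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("A", 10, 10, "PF00002", "DomB"))),
    list(expected = exp_row("DDI", "PF00001", "PF00002",
                            "intramolecular", "heterodomain", nhy = 1L,
                            nvdw = 1L, ncontacts = 1L),
         expectedLigands = character(0)))

  fx$vdw_ddi_intra <- c(buildFixture(
    rbind(p("A", 1, "ALA", "CB", "C", 0, 0, 0),
          p("A", 10, "ALA", "CB", "C", 4.15, 0, 0)),
    contacts = data.frame(a = 1L, b = 2L, type = "vdw"),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("A", 10, 10, "PF00002", "DomB"))),
    list(expected = exp_row("DDI", "PF00001", "PF00002",
                            "intramolecular", "heterodomain", nvdw = 1L,
                            ncontacts = 1L),
         expectedLigands = character(0)))

  # --- homodomain relation on both topologies ---
  fx$homo_ddi_inter <- c(buildFixture(
    rbind(p("A", 1, "ALA", "CB", "C", 0, 0, 0),
          p("B", 1, "ALA", "CB", "C", 4.15, 0, 0)),
    contacts = data.frame(a = 1L, b = 2L, type = "vdw"),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("B", 1, 1, "PF00001", "DomA"))),
    list(expected = exp_row("DDI", "PF00001", "PF00001",
                            "intermolecular", "homodomain", nvdw = 1L,
                            ncontacts = 1L),
         expectedLigands = character(0)))

  fx$homo_ddi_intra <- c(buildFixture(
    rbind(p("A", 1, "ALA", "CB", "C", 0, 0, 0),
          p("A", 50, "ALA", "CB", "C", 4.15, 0, 0)),
    contacts = data.frame(a = 1L, b = 2L, type = "vdw"),
    regions = rbind(reg("A", 1, 1, "PF00001", "DomA"),
                    reg("A", 50, 50, "PF00001", "DomA"))),
    list(expected = exp_row("DDI", "PF00001", "PF00001",
                            "intramolecular", "homodomain", nvdw = 1L,
                            ncontacts = 1L),
         expectedLigands = character(0)))

  # two domains abutting on one chain: their backbone peptide bond is
  # sequence-adjacent and must not count as interaction evidence
  fx$adjacent_backbone <- c(buildFixture(
    rbind(p("A", 1, "GLY", "C", "C", 0, 0, 0),
          p("A", 2, "GLY", "N", "N", 1.33, 0, 0)),
    regions = rbind(reg("A", 1, 1, "PF00010", "DomL"),
                    reg("A", 2, 2, "PF00011", "DomR"))),
    list(expected = noInteractions, expectedLigands = character(0)))

  # --- DLI across the bond classes and both topologies ---
  fx$cov_dli_inter <- c(buildFixture(
    rbind(p("A", 1, "CYS", "SG", "S", 0, 0, 0),
          p("B", 101, "LGS", "S1", "S", 1.05, 0, 0, record = "HETATM")),
    contacts = data.frame(a = 1L, b = 2L, type = "covalent"),
    regions = reg("A", 1, 1, "PF00001", "DomA")),
    list(expected = exp_row("DLI", "PF00001", "LGS", "intermolecular",
                            ".", ncov = 1L, ncontacts = 1L),
         expectedLigands = "LGS"))

  fx$elec_dli_intra <- c(buildFixture(
    rbind(p("A", 1, "GLU", "OE1", "O", 0, 0, 0),
          p("A", 101, "ZN", "ZN", "ZN", 2.1, 0, 0, record = "HETATM")),
    contacts = data.frame(a = 1L, b = 2L, type = "electrostatic"),
    regions = reg("A", 1, 1, "PF00001", "DomA")),
    list(expected = exp_row("DLI", "PF00001", "ZN", "intramolecular",
                            ".", nel = 1L, ncontacts = 1L),
         expectedLigands = "ZN"))

  fx$hyd_dli_inter <- c(buildFixture(
    rbind(p("A", 1, "ALA", "C", "C", 1.23, 0, 0),
          p("A", 1, "ALA", "O", "O", 0, 0, 0),
          p("B", 101, "LGN", "N1", "N", -1.5, 2.5981, 0,
            record = "HETATM")),
    contacts = data.frame(a = c(3L, 3L), b = c(2L, 1L),
                          type = c("hydrogen", "vdw")),
    regions = reg("A", 1, 1, "PF00001", "DomA")),
    list(expected = exp_row("DLI", "PF00001", "LGN", "intermolecular",
                            ".", nhy = 1L, nvdw = 1L, ncontacts = 1L),
         expectedLigands = "LGN"))

  fx$vdw_dli_intra <- c(buildFixture(
    rbind(p("A", 1, "ALA", "CB", "C", 0, 0, 0),
          p("A", 101, "LGC", "C1", "C", 4.15, 0, 0, record = "HETATM")),
    contacts = data.frame(a = 1L, b = 2L, type = "vdw"),
    regions = reg("A", 1, 1, "PF00001", "DomA")),
    list(expected = exp_row("DLI", "PF00001", "LGC", "intramolecular",
                            ".", nvdw = 1L, ncontacts = 1L),
         expectedLigands = "LGC"))

  # --- all four ligand-exclusion branches + bridging-metal control ---
  # every HETATM here sits inside a vdW window of the domain atom, so
  # each would yield a DLI if not excluded
  fx$ligand_rules <- c(buildFixture(
    rbind(p("A", 1, "ALA", "CB", "C", 0, 0, 0),
          p("A", 201, "HOH", "O", "O", 4.0, 0, 0, record = "HETATM"),
          p("A", 202, "A", "C1", "C", 0, 4.15, 0, record = "HETATM"),
          p("A", 2, "MSE", "SE", "SE", 0, 0, -4.2, record = "HETATM"),
          p("A", 301, "ABC", "C1", "C", 0, -4.15, 0, record = "HETATM"),
          p("B", 401, "ZN", "ZN", "ZN", 0, 0, 4.4, record = "HETATM")),
    regions = reg("A", 1, 1, "PF00001", "DomA"),
    modres = data.frame(chain = "A", resno = 2L, icode = "",
                        resname = "MSE", stringsAsFactors = FALSE),
    links = data.frame(name1 = c("C1", "ZN"),
                       resname1 = c("ABC", "ZN"),
                       chain1 = c("A", "B"), resno1 = c(301L, 401L),
                       icode1 = "", name2 = "CB", resname2 = "ALA",
                       chain2 = "A", resno2 = 1L, icode2 = "",
                       stringsAsFactors = FALSE)),
    list(expected = exp_row("DLI", "PF00001", "ZN", "intermolecular",
                            ".", nvdw = 1L, ncontacts = 1L),
         expectedLigands = "ZN"))

  # --- synthetic stand-in for a minimal all-vdW two-domain interface:
  # five residues of one domain against four of the next domain on the
  # same chain, every contact van der Waals, no higher-order bonds ---
  sh3x <- c(0, 6, 12, 18, 24); sh3no <- c(83, 85, 90, 95, 98)
  sh2x <- c(3, 9, 15, 21);     sh2no <- c(128, 131, 158, 160)
  sh <- rbind(
    do.call(rbind, lapply(seq_along(sh3x), function(i)
      p("A", sh3no[i], "ALA", "CB", "C", sh3x[i], 0, 0))),
    do.call(rbind, lapply(seq_along(sh2x), function(i)
      p("A", sh2no[i], "ALA", "CB", "C", sh2x[i], 3.6, 0))))
  shContacts <- data.frame(
    a = c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L),
    b = 5L + c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
    type = "vdw", stringsAsFactors = FALSE)
  fx$synthetic_sh3_sh2 <- c(buildFixture(
    sh, contacts = shContacts,
    regions = rbind(reg("A", 65, 119, "PF00018", "SH3_1", 1e-15),
                    reg("A", 121, 210, "PF00017", "SH2", 1e-20)),
    pdbId = "SYN1"),
    list(expected = exp_row("DDI", "PF00017", "PF00018",
                            "intramolecular", "heterodomain", nvdw = 8L,
                            ncontacts = 8L),
         expectedLigands = character(0)))

  fx
}
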