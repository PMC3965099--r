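# Minimal atom constructor for the scalar classification API.
mkatom <- function(x, y, z, cov, vdw, charge = 0, donor = 0,
                   acceptor = 0) {
  list(x = x, y = y, z = z, covalent_radius = cov, vdw_radius = vdw,
       charge = charge, donor = donor, acceptor = acceptor)
}

# One-row atom data.frame in the structure layout, for detectBonds().
atomRow <- function(serial, name, resname, chain, resno, x, y, z,
                    element, record = "ATOM", icode = "") {
  data.frame(record = record, serial = as.integer(serial), name = name,
             altloc = "", resname = resname, chain = chain,
             resno = as.integer(resno), icode = icode, x = x, y = y,
             z = z, occupancy = 1, element = element,
             stringsAsFactors = FALSE)
}

# Interaction inventory (one row per call) from a runPipeline() result.
inventoryFromResult <- function(res) {
  rows <- lapply(res$interactions, function(x) {
    n <- x@nBondsByType
    data.frame(
      kind = x@kind, family_a = x@partnerA@region$pfam_acc,
      family_b_or_het = if (x@kind == "DDI")
        x@partnerB@region$pfam_acc else x@partnerB@hetCode,
      topology = x@topology,
      relation = ifelse(is.na(x@relation), ".", x@relation),
      n_covalent = n[["covalent"]],
      n_electrostatic = n[["electrostatic"]],
      n_hydrogen = n[["hydrogen"]],
      n_residue_pairs_vdw = n[["vdw_residue_pairs"]],
      n_contacts = nrow(x@residueContacts), stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(fixtureSuite()[[1L]]$expected[0L, ])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Same inventory reconstructed from the written TSV files.
inventoryFromFiles <- function(outDir) {
  it <- utils::read.delim(file.path(outDir, "interactions.tsv"),
                          colClasses = "character")
  rc <- utils::read.delim(file.path(outDir, "residue_contacts.tsv"),
                          colClasses = "character")
  if (nrow(it) == 0L) return(fixtureSuite()[[1L]]$expected[0L, ])
  data.frame(kind = it$kind, family_a = it$family_a,
             family_b_or_het = it$family_b_or_het,
             topology = it$topology, relation = it$relation,
             n_covalent = as.integer(it$n_covalent),
             n_electrostatic = as.integer(it$n_electrostatic),
             n_hydrogen = as.integer(it$n_hydrogen),
             n_residue_pairs_vdw = as.integer(it$n_residue_pairs_vdw),
             n_contacts = as.integer(table(rc$interaction_id)[
               it$interaction_id]),
             stringsAsFactors = FALSE)
}

expect_inventory <- function(actual, expected) {
  rownames(actual) <- rownames(expected) <- NULL
  expect_equal(actual, expected, ignore_attr = TRUE)
}

# Random overlapping-region generator for overlap-resolution checks.
randomRegions <- function(n, chain = "A") {
  start <- sample.int(60L, n, replace = TRUE)
  len <- sample.int(30L, n, replace = TRUE)
  data.frame(pdb_id = "XXXX", chain = chain, start = start,
             start_icode = "", end = start + len, end_icode = "",
             pfam_acc = sprintf("PF%05d", sample.int(99999L, n)),
             pfam_id = sprintf("fam%d", seq_len(n)),
             e_value = 10^stats::runif(n, -30, -1),
             stringsAsFactors = FALSE)
}

# Independent brute-force oracle for overlap resolution: enumerate
# every overlap-free subset and keep the one whose ascending
# significance sequence is lexicographically dominant (most significant
# first, longer on ties of the whole prefix).
bruteForceResolve <- function(regions) {
  n <- nrow(regions)
  overlap <- function(i, j)
    regions$end[i] >= regions$start[j] & regions$end[j] >= regions$start[i]
  subsets <- lapply(seq_len(2^n) - 1L, function(mask)
    which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L))
  free <- Filter(function(s) {
    if (length(s) < 2L) return(TRUE)
    all(!apply(utils::combn(s, 2L), 2L,
               function(p) overlap(p[1L], p[2L])))
  }, subsets)
  better <- function(a, b) {           # TRUE if subset a dominates b
    ea <- sort(regions$e_value[a]); eb <- sort(regions$e_value[b])
    k <- min(length(ea), length(eb))
    if (k > 0L) for (i in seq_len(k)) {
      if (ea[i] < eb[i]) return(TRUE)
      if (ea[i] > eb[i]) return(FALSE)
    }
    length(ea) > length(eb)
  }
  best <- free[[1L]]
  for (s in free[-1L]) if (better(s, best)) best <- s
  regions[sort(best), , drop = FALSE]
}

noOverlaps <- function(regions) {
  n <- nrow(regions)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    if (regions$end[i] >= regions$start[j] &&
        regions$end[j] >= regions$start[i]) return(FALSE)
  TRUE
}
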