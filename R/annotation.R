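#' Read a domain-region annotation table
#'
#' Tab-separated columns: `pdb_id chain start start_icode end end_icode
#' pfam_acc pfam_id e_value`, with "." standing for a blank insertion
#' code.  Residue ranges are inclusive at both endpoints in PDB author
#' numbering.  An E-value of 0 is accepted as a curated-annotation
#' sentinel that always wins overlap resolution.
#'
#' @param input path to a TSV file, or its content as character lines.
#' @param header whether the first line is a header (auto-detected by
#'   default from a leading `pdb_id` field).
#' @return data.frame of domain regions.
#' @export
readDomainRegions <- function(input, header = NA) {
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input))
    input <- readLines(input, warn = FALSE)
  else if (length(input) == 1L && grepl("\n", input, fixed = TRUE))
    input <- strsplit(input, "\n", fixed = TRUE)[[1L]]
  input <- input[nzchar(trimws(input))]
  if (is.na(header)) header <- length(input) > 0L &&
      startsWith(input[1L], "pdb_id")
  if (isTRUE(header)) input <- input[-1L]
  if (length(input) == 0L) return(emptyRegions())
  f <- strsplit(input, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad) > 0L)
    stop(sprintf("domain TSV line %d: expected 9 tab-separated fields",
                 bad[1L] + as.integer(header)))
  m <- do.call(rbind, f)
  dot <- function(v) ifelse(v == ".", "", v)
  reg <- data.frame(pdb_id = m[, 1L], chain = m[, 2L],
                    start = as.integer(m[, 3L]),
                    start_icode = dot(m[, 4L]),
                    end = as.integer(m[, 5L]), end_icode = dot(m[, 6L]),
                    pfam_acc = m[, 7L], pfam_id = m[, 8L],
                    e_value = as.numeric(m[, 9L]),
                    stringsAsFactors = FALSE)
  if (any(is.na(reg$start) | is.na(reg$end) | is.na(reg$e_value)))
    stop("domain TSV: non-numeric start/end/e_value field")
  if (any(reg$e_value < 0)) stop("domain TSV: e_value must be >= 0")
  if (any(reg$end < reg$start))
    stop("domain TSV: region end before start")
  reg
}

emptyRegions <- function() {
  data.frame(pdb_id = character(0), chain = character(0),
             start = integer(0), start_icode = character(0),
             end = integer(0), end_icode = character(0),
             pfam_acc = character(0), pfam_id = character(0),
             e_value = numeric(0), stringsAsFactors = FALSE)
}

#' Drop regions referring to obsolete structures
#'
#' Keeps exactly the regions whose pdb_id is in the valid set, in their
#' original order.  This mirrors the synchronisation step that removes
#' references to withdrawn PDB entries from a stale mapping.
#'
#' @param regions data.frame from [readDomainRegions()].
#' @param validPdbIds character vector of current entry identifiers.
#' @return Filtered data.frame.
#' @export
filterObsolete <- function(regions, validPdbIds) {
  out <- regions[regions$pdb_id %in% validPdbIds, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping domain matches by significance
#'
#' Regions on one (pdb_id, chain) are filtered so that no two retained
#' regions overlap (closed-interval intersection in author numbering):
#' regions are sorted by ascending E-value and accepted greedily, any
#' region overlapping an already accepted one being discarded.  Exact
#' E-value ties are broken in favour of the longer region, then by
#' lexicographic accession.  The result is that whenever two input
#' regions overlap, the more significant match survives.
#'
#' @param regions data.frame of regions sharing one (pdb_id, chain).
#' @return Overlap-free data.frame, in ascending E-value order.
#' @details Idempotent: applying the filter to its own output is the
#'   identity.  Insertion-code ranges are ordered by (resno, icode) with
#'   a blank icode sorting before "A".
#' @export
resolveOverlaps <- function(regions) {
  if (nrow(regions) <= 1L) {
    rownames(regions) <- NULL
    return(regions)
  }
  if (length(unique(paste(regions$pdb_id, regions$chain))) > 1L)
    stop("resolveOverlaps expects regions on a single (pdb_id, chain)")
  len <- regions$end - regions$start
  ord <- order(regions$e_value, -len, regions$pfam_acc)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L || !any(regionsOverlap(regions[i, ],
                                                  regions[keep, ])))
      keep <- c(keep, i)
  }
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Closed-interval overlap of one region against each row of `others`,
# in (resno, icode) author-numbering order.
regionsOverlap <- function(region, others) {
  ge <- function(n1, i1, n2, i2)         # (n1,i1) >= (n2,i2)
    n1 > n2 | (n1 == n2 & i1 >= i2)
  ge(others$end, others$end_icode, region$start, region$start_icode) &
    ge(region$end, region$end_icode, others$start, others$start_icode)
}

#' Resolve domain regions onto structure residues
#'
#' Each region becomes one [DomainInstance-class] containing every
#' ATOM-record residue on its chain whose (resno, icode) lies within the
#' closed range [start, end].  Regions on chains absent from the
#' structure, or resolving to zero residues, are dropped with a warning
#' (coordinate/mapping mismatches are expected in the wild).
#'
#' @param structure a [PDBStructure-class].
#' @param regions overlap-free data.frame of regions (per chain).
#' @return List of [DomainInstance-class] objects.
#' @export
attachDomains <- function(structure, regions) {
  at <- structure@atoms
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, , drop = FALSE]
    onChain <- at$record == "ATOM" & at$chain == r$chain
    if (!any(onChain)) {
      warning(sprintf("region %s %d-%d: chain '%s' absent from structure; dropped",
                      r$pfam_acc, r$start, r$end, r$chain))
      next
    }
    ge <- function(n1, i1, n2, i2) n1 > n2 | (n1 == n2 & i1 >= i2)
    inRange <- onChain &
      ge(at$resno, at$icode, r$start, r$start_icode) &
      ge(r$end, r$end_icode, at$resno, at$icode)
    if (!any(inRange)) {
      warning(sprintf("region %s %s:%d-%d resolves to zero residues; dropped",
                      r$pfam_acc, r$chain, r$start, r$end))
      next
    }
    idx <- which(inRange)
    keys <- unique(residueKey(at$chain[idx], at$resno[idx], at$icode[idx]))
    out[[length(out) + 1L]] <-
      new("DomainInstance", region = r, residueKeys = keys,
          atomIdx = as.integer(idx))
  }
  out
}

residueKey <- function(chain, resno, icode) {
  paste(chain, resno, icode, sep = "|")
}

# Aqueous-solvent and nucleic-acid chemical component codes excluded
# from the ligand definition.
SOLVENT_CODES <- c("HOH", "DOD", "H2O", "WAT")
NUCLEIC_CODES <- c("A", "C", "G", "U", "I", "N",
                   "DA", "DC", "DG", "DT", "DU", "DI", "DN")

#' Identify small-molecule ligands in a structure
#'
#' A ligand is any HETATM residue that is not (a) an aqueous solvent,
#' (b) a nucleic-acid component, (c) listed in MODRES, or (d) joined by
#' a LINK record to a polymer (ATOM-record) atom of the same chain (a
#' covalently modified residue).  A LINK to a different chain's polymer
#' does not exclude it, so bridging metals and glycans remain ligands.
#'
#' @param structure a [PDBStructure-class].
#' @param solventExtra,nucleicExtra additional component codes to
#'   exclude beyond the built-in lists.
#' @return List of [LigandInstance-class] objects, in file order.
#' @export
identifyLigands <- function(structure, solventExtra = character(0),
                            nucleicExtra = character(0)) {
  at <- structure@atoms
  het <- at$record == "HETATM"
  if (!any(het)) return(list())
  solvent <- c(SOLVENT_CODES, toupper(solventExtra))
  nucleic <- c(NUCLEIC_CODES, toupper(nucleicExtra))
  key <- residueKey(at$chain, at$resno, at$icode)
  out <- list()
  for (k in unique(key[het])) {
    idx <- which(key == k & het)
    code <- at$resname[idx[1L]]
    if (code %in% solvent || code %in% nucleic) next
    if (isModres(structure, at$chain[idx[1L]], at$resno[idx[1L]],
                 at$icode[idx[1L]], code)) next
    if (linkedToSameChainPolymer(structure, at$chain[idx[1L]],
                                 at$resno[idx[1L]], at$icode[idx[1L]],
                                 code)) next
    out[[length(out) + 1L]] <-
      new("LigandInstance", hetCode = code, chain = at$chain[idx[1L]],
          resno = at$resno[idx[1L]], icode = at$icode[idx[1L]],
          atomIdx = as.integer(idx))
  }
  out
}

isModres <- function(structure, chain, resno, icode, code) {
  mr <- structure@modres
  any(mr$chain == chain & mr$resno == resno & mr$icode == icode &
      mr$resname == code)
}

linkedToSameChainPolymer <- function(structure, chain, resno, icode, code) {
  lk <- structure@links
  if (nrow(lk) == 0L) return(FALSE)
  at <- structure@atoms
  polymerAtom <- function(ch, no, ic) {
    any(at$record == "ATOM" & at$chain == ch & at$resno == no &
        at$icode == ic)
  }
  for (i in seq_len(nrow(lk))) {
    if (lk$chain1[i] == chain && lk$resno1[i] == resno &&
        lk$icode1[i] == icode && lk$resname1[i] == code &&
        lk$chain2[i] == chain &&
        polymerAtom(lk$chain2[i], lk$resno2[i], lk$icode2[i]))
      return(TRUE)
    if (lk$chain2[i] == chain && lk$resno2[i] == resno &&
        lk$icode2[i] == icode && lk$resname2[i] == code &&
        lk$chain1[i] == chain &&
        polymerAtom(lk$chain1[i], lk$resno1[i], lk$icode1[i]))
      return(TRUE)
  }
  FALSE
}
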