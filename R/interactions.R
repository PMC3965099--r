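#' Call domain--domain and domain--ligand interactions
#'
#' Runs bond detection over every unordered pair of domain instances and
#' every (domain, ligand) pair, and emits one [Interaction-class] per
#' pair joined by at least one bond -- the one-bond rule; no minimum
#' interface size is imposed.  Bonds between residues adjacent in
#' sequence on the same chain are skipped, so two domains merely
#' abutting on a chain do not "interact" through their shared backbone
#' peptide bond.  Topology is intramolecular when both partners lie on
#' one chain; a DDI is homodomain when both instances carry the same
#' family accession.  Van der Waals bonds are aggregated to
#' residue-pair flags (see [aggregateResidueContacts()]).
#'
#' @param structure the [PDBStructure-class] the instances live on.
#' @param domains list of [DomainInstance-class] (overlap-free per chain).
#' @param ligands list of [LigandInstance-class].
#' @param params a [ParameterSet-class].
#' @param criteria a [BondCriteria-class].
#' @return List of [Interaction-class] objects, deterministically
#'   ordered (DDI before DLI, then by partner identifiers).
#' @export
callInteractions <- function(structure, domains, ligands = list(),
                             params = defaultParams(),
                             criteria = bondCriteria()) {
  at <- structure@atoms
  chainPos <- polymerPositions(structure)
  out <- list()
  nd <- length(domains)
  if (nd >= 2L) {
    for (i in seq_len(nd - 1L)) {
      for (j in seq.int(i + 1L, nd)) {
        bonds <- detectBonds(at[domains[[i]]@atomIdx, , drop = FALSE],
                             at[domains[[j]]@atomIdx, , drop = FALSE],
                             params, criteria)
        bonds <- dropAdjacentResidueBonds(bonds, chainPos)
        if (nrow(bonds) == 0L) next
        # canonical partner order: by accession, chain, then start
        ki <- domainSortKey(domains[[i]])
        kj <- domainSortKey(domains[[j]])
        out[[length(out) + 1L]] <- if (kj < ki)
          makeInteraction("DDI", domains[[j]], domains[[i]],
                          swapBondSides(bonds))
        else makeInteraction("DDI", domains[[i]], domains[[j]], bonds)
      }
    }
  }
  for (d in domains) {
    for (lig in ligands) {
      bonds <- detectBonds(at[d@atomIdx, , drop = FALSE],
                           at[lig@atomIdx, , drop = FALSE],
                           params, criteria)
      if (nrow(bonds) == 0L) next
      out[[length(out) + 1L]] <- makeInteraction("DLI", d, lig, bonds)
    }
  }
  out[order(vapply(out, interactionSortKey, character(1)))]
}

makeInteraction <- function(kind, a, b, bonds) {
  chainsA <- unique(sub("\\|.*", "", a@residueKeys))
  if (kind == "DDI") {
    chainsB <- unique(sub("\\|.*", "", b@residueKeys))
    relation <- if (identical(a@region$pfam_acc, b@region$pfam_acc))
      "homodomain" else "heterodomain"
  } else {
    chainsB <- b@chain
    relation <- NA_character_
  }
  topology <- if (length(union(chainsA, chainsB)) == 1L)
    "intramolecular" else "intermolecular"
  contacts <- aggregateResidueContacts(bonds)
  counts <- c(covalent = sum(bonds$bond_type == "covalent"),
              electrostatic = sum(bonds$bond_type == "electrostatic"),
              hydrogen = sum(bonds$bond_type == "hydrogen"),
              vdw_residue_pairs = sum(contacts$vdw_flag))
  new("Interaction", kind = kind, partnerA = a, partnerB = b,
      topology = topology, relation = relation,
      bonds = bonds[bonds$bond_type != "vdw", , drop = FALSE],
      residueContacts = contacts,
      nBondsByType = as.integer(counts) |>
        stats::setNames(names(counts)))
}

domainSortKey <- function(d) {
  paste(d@region$pfam_acc, d@region$chain, sprintf("%06d", d@region$start))
}

swapBondSides <- function(bonds) {
  a <- grep("_a$", names(bonds))
  b <- grep("_b$", names(bonds))
  names(bonds)[c(a, b)] <- c(sub("_a$", "_b", names(bonds)[a]),
                             sub("_b$", "_a", names(bonds)[b]))
  bonds <- bonds[, names(emptyBonds()), drop = FALSE]
  ord <- order(bonds$chain_a, bonds$resno_a, bonds$icode_a, bonds$name_a,
               bonds$serial_a, bonds$chain_b, bonds$resno_b,
               bonds$icode_b, bonds$name_b, bonds$serial_b)
  bonds <- bonds[ord, , drop = FALSE]
  rownames(bonds) <- NULL
  bonds
}

interactionSortKey <- function(x) {
  pb <- if (x@kind == "DDI")
    paste(x@partnerB@region$pfam_acc, x@partnerB@region$chain,
          sprintf("%06d", x@partnerB@region$start))
  else paste(x@partnerB@hetCode, x@partnerB@chain,
             sprintf("%06d", x@partnerB@resno))
  paste(x@kind, x@partnerA@region$pfam_acc, x@partnerA@region$chain,
        sprintf("%06d", x@partnerA@region$start), pb)
}

# Ordinal position of every polymer residue along its chain (file
# order); two residues are sequence-adjacent when consecutive in this
# order and their author numbers differ by at most one.
polymerPositions <- function(structure) {
  at <- structure@atoms
  poly <- at[at$record == "ATOM", , drop = FALSE]
  key <- residueKey(poly$chain, poly$resno, poly$icode)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = poly$chain[first],
             resno = poly$resno[first],
             pos = stats::ave(seq_len(sum(first)), poly$chain[first],
                              FUN = seq_along),
             stringsAsFactors = FALSE)
}

dropAdjacentResidueBonds <- function(bonds, chainPos) {
  if (nrow(bonds) == 0L) return(bonds)
  ka <- residueKey(bonds$chain_a, bonds$resno_a, bonds$icode_a)
  kb <- residueKey(bonds$chain_b, bonds$resno_b, bonds$icode_b)
  pa <- chainPos$pos[match(ka, chainPos$key)]
  pb <- chainPos$pos[match(kb, chainPos$key)]
  adjacent <- bonds$chain_a == bonds$chain_b &
    !is.na(pa) & !is.na(pb) & abs(pa - pb) == 1L &
    abs(bonds$resno_a - bonds$resno_b) <= 1L
  out <- bonds[!adjacent, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate atomic bonds into residue-level contacts
#'
#' One record per unordered residue pair having at least one bond.
#' Non-vdw ("higher order") bonds are retained individually; van der
#' Waals bonds are collapsed to a per-residue-pair flag, so individual
#' vdw atom pairs are not stored.  Each contact also carries the most
#' energetically significant bond type present, under the precedence
#' covalent > electrostatic > hydrogen > vdw used by the interface
#' display.
#'
#' @param bonds data.frame from [detectBonds()] for one molecule pair.
#' @return data.frame with residue identity columns for both sides,
#'   `bond_types_present` (comma-joined, in precedence order),
#'   `n_higher_order`, `vdw_flag` and `most_significant_bond`.
#' @export
aggregateResidueContacts <- function(bonds) {
  empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                      icode_a = character(0), resname_a = character(0),
                      chain_b = character(0), resno_b = integer(0),
                      icode_b = character(0), resname_b = character(0),
                      bond_types_present = character(0),
                      n_higher_order = integer(0), vdw_flag = logical(0),
                      most_significant_bond = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(bonds) == 0L) return(empty)
  ka <- residueKey(bonds$chain_a, bonds$resno_a, bonds$icode_a)
  kb <- residueKey(bonds$chain_b, bonds$resno_b, bonds$icode_b)
  pair <- paste(ka, kb, sep = " :: ")
  rows <- lapply(unique(pair), function(p) {
    sel <- bonds[pair == p, , drop = FALSE]
    present <- BOND_TYPES[BOND_TYPES %in% sel$bond_type]
    data.frame(chain_a = sel$chain_a[1L], resno_a = sel$resno_a[1L],
               icode_a = sel$icode_a[1L], resname_a = sel$resname_a[1L],
               chain_b = sel$chain_b[1L], resno_b = sel$resno_b[1L],
               icode_b = sel$icode_b[1L], resname_b = sel$resname_b[1L],
               bond_types_present = paste(present, collapse = ","),
               n_higher_order = sum(sel$bond_type != "vdw"),
               vdw_flag = any(sel$bond_type == "vdw"),
               most_significant_bond = present[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$chain_a, out$resno_a, out$icode_a, out$chain_b,
               out$resno_b, out$icode_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface residues of an interaction
#'
#' Per residue position on each side of the interface, the most
#' energetically significant bond class that position participates in
#' (precedence covalent > electrostatic > hydrogen > vdw) -- the
#' per-position colouring of a 2D interface display.
#'
#' @param interaction an [Interaction-class].
#' @return data.frame with side ("A"/"B"), chain, resno, icode, resname
#'   and most_significant_bond; one row per participating residue.
#' @export
interfaceResidues <- function(interaction) {
  rc <- interaction@residueContacts
  one <- function(side) {
    cols <- paste0(c("chain", "resno", "icode", "resname"), "_", side)
    df <- rc[, c(cols, "most_significant_bond")]
    names(df) <- c("chain", "resno", "icode", "resname", "bond")
    df$rank <- match(df$bond, BOND_TYPES)
    key <- residueKey(df$chain, df$resno, df$icode)
    best <- tapply(seq_len(nrow(df)), key, function(i)
      i[which.min(df$rank[i])])
    df <- df[unlist(best), , drop = FALSE]
    data.frame(side = toupper(side), chain = df$chain, resno = df$resno,
               icode = df$icode, resname = df$resname,
               most_significant_bond = df$bond, stringsAsFactors = FALSE)
  }
  out <- rbind(one("a"), one("b"))
  ord <- order(out$side, out$chain, out$resno, out$icode)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally interactions into the topology-by-relation grid
#'
#' Fills the 2 x 3 grid \{intramolecular, intermolecular\} x
#' \{homodomain, heterodomain, ligand\}; every interaction increments
#' exactly one cell, so the cells sum to the number of interactions.
#'
#' @param interactions list of [Interaction-class].
#' @return Integer matrix with rows intramolecular/intermolecular and
#'   columns homodomain/heterodomain/ligand.
#' @export
summarizeInteractions <- function(interactions) {
  m <- matrix(0L, nrow = 2L, ncol = 3L,
              dimnames = list(c("intramolecular", "intermolecular"),
                              c("homodomain", "heterodomain", "ligand")))
  for (x in interactions) {
    col <- if (x@kind == "DLI") "ligand" else x@relation
    m[x@topology, col] <- m[x@topology, col] + 1L
  }
  m
}
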