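#' Access the atom table of a structure
#'
#' @param x a [PDBStructure-class].
#' @return data.frame of atoms (one row per atom).
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)

#' Residue table of a structure
#'
#' One row per (chain, resno, icode) residue, in file order.
#'
#' @param x a [PDBStructure-class].
#' @return data.frame with chain, resno, icode, resname, record and the
#'   number of atoms.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname residues
#' @export
setMethod("residues", "PDBStructure", function(x) {
  at <- x@atoms
  key <- residueKey(at$chain, at$resno, at$icode)
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             icode = at$icode[first], resname = at$resname[first],
             record = at$record[first],
             n_atoms = as.integer(table(key)[key[first]]),
             stringsAsFactors = FALSE)
})

#' PDB identifier of a structure
#' @param x a [PDBStructure-class].
#' @return single character string ("" if unknown).
#' @export
setGeneric("pdbId", function(x) standardGeneric("pdbId"))

#' @rdname pdbId
#' @export
setMethod("pdbId", "PDBStructure", function(x) x@pdbId)

setMethod("show", "PDBStructure", function(object) {
  at <- object@atoms
  cat(sprintf("PDBStructure %s: %d atoms (%d ATOM, %d HETATM), %d chains\n",
              if (nzchar(object@pdbId)) object@pdbId else "<unnamed>",
              nrow(at), sum(at$record == "ATOM"),
              sum(at$record == "HETATM"), length(unique(at$chain))))
  cat(sprintf("  %d MODRES, %d LINK records\n",
              nrow(object@modres), nrow(object@links)))
})

setMethod("show", "ParameterSet", function(object) {
  cat(sprintf("ParameterSet: %d atom-type entries, %d element defaults\n",
              nrow(object@entries), nrow(object@defaults)))
})

setMethod("show", "BondCriteria", function(object) {
  cat(sprintf(paste0("BondCriteria: H-bond D-A < %.2f A, acceptor angle",
                     " [%g, %g] deg, vdW margin %.2f A\n"),
              object@hbondMaxDist, object@hbondAngleMin,
              object@hbondAngleMax, object@vdwMargin))
})

setMethod("show", "DomainInstance", function(object) {
  r <- object@region
  cat(sprintf("DomainInstance %s (%s) chain %s %d%s-%d%s: %d residues, %d atoms\n",
              r$pfam_acc, r$pfam_id, r$chain, r$start,
              ifelse(nzchar(r$start_icode), r$start_icode, ""),
              r$end, ifelse(nzchar(r$end_icode), r$end_icode, ""),
              length(object@residueKeys), length(object@atomIdx)))
})

setMethod("show", "LigandInstance", function(object) {
  cat(sprintf("LigandInstance %s chain %s %d%s: %d atoms\n",
              object@hetCode, object@chain, object@resno,
              ifelse(nzchar(object@icode), object@icode, ""),
              length(object@atomIdx)))
})

setMethod("show", "Interaction", function(object) {
  n <- object@nBondsByType
  partner <- if (object@kind == "DDI")
    object@partnerB@region$pfam_acc else object@partnerB@hetCode
  cat(sprintf("%s %s -- %s [%s%s]\n", object@kind,
              object@partnerA@region$pfam_acc, partner, object@topology,
              if (!is.na(object@relation))
                paste0(", ", object@relation) else ""))
  cat(sprintf("  bonds: %d covalent, %d electrostatic, %d hydrogen; %d residue pairs with vdW flag\n",
              n[["covalent"]], n[["electrostatic"]], n[["hydrogen"]],
              n[["vdw_residue_pairs"]]))
  cat(sprintf("  %d residue contacts\n", nrow(object@residueContacts)))
})
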