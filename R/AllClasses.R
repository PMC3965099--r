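#' @import methods
NULL

CHEM_COLS <- c("key_residue", "key_atom", "covalent_radius", "vdw_radius",
               "charge", "donor", "acceptor")

BOND_TYPES <- c("covalent", "electrostatic", "hydrogen", "vdw")

ATOM_COLS <- c("record", "serial", "name", "altloc", "resname", "chain",
               "resno", "icode", "x", "y", "z", "occupancy", "element")

#' Atom chemistry parameter set
#'
#' Holds the per-atom-type chemical parameters (covalent and van der Waals
#' radii in Angstrom, formal charge sign, hydrogen-bond donor/acceptor
#' flags) that drive every bond classification.  Residue+atom specific
#' entries override per-element defaults, so that any atom with a
#' recognised element always resolves to some parameter row.
#'
#' @slot entries data.frame of residue+atom specific rows.
#' @slot defaults data.frame of per-element fallback rows.
#' @seealso [loadParams()], [defaultParams()], [lookupChemistry()]
#' @exportClass ParameterSet
setClass("ParameterSet",
         slots = c(entries = "data.frame", defaults = "data.frame"))

validChemTable <- function(df, what) {
  if (!all(CHEM_COLS %in% names(df)))
    return(sprintf("%s must have columns: %s", what,
                   paste(CHEM_COLS, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (!is.numeric(df$covalent_radius) || !is.numeric(df$vdw_radius))
    return("radii must be numeric")
  if (any(!is.finite(df$covalent_radius)) || any(!is.finite(df$vdw_radius)))
    return("radii must be finite")
  if (any(df$covalent_radius <= 0) || any(df$vdw_radius <= 0))
    return("radii must be > 0")
  if (any(df$covalent_radius >= df$vdw_radius))
    return("covalent radius must be < van der Waals radius for every entry")
  if (!all(df$charge %in% c(-1L, 0L, 1L)))
    return("charge must be -1, 0 or +1")
  if (!all(df$donor %in% c(0L, 1L)) || !all(df$acceptor %in% c(0L, 1L)))
    return("donor/acceptor must be 0/1 flags")
  key <- paste(df$key_residue, df$key_atom)
  if (anyDuplicated(key))
    return(sprintf("duplicate key in %s: %s", what, key[duplicated(key)][1L]))
  TRUE
}

setValidity("ParameterSet", function(object) {
  v <- validChemTable(object@entries, "entries")
  if (!isTRUE(v)) return(v)
  validChemTable(object@defaults, "element defaults")
})

#' Geometric bond-classification criteria
#'
#' Thresholds for the hydrogen-bond and van der Waals rules.  Defaults:
#' donor--acceptor distance < 3.6 Angstrom, acceptor-side angle within
#' [90, 140] degrees, and a 1.5 Angstrom margin above the van der Waals
#' radius sum for van der Waals contacts.
#'
#' @slot hbondMaxDist maximum donor--acceptor distance (Angstrom).
#' @slot hbondAngleMin,hbondAngleMax acceptor-angle window (degrees).
#' @slot vdwMargin width of the van der Waals window (Angstrom).
#' @exportClass BondCriteria
setClass("BondCriteria",
         slots = c(hbondMaxDist = "numeric", hbondAngleMin = "numeric",
                   hbondAngleMax = "numeric", vdwMargin = "numeric"))

setValidity("BondCriteria", function(object) {
  len <- c(object@hbondMaxDist, object@vdwMargin)
  if (any(!is.finite(len)) || any(len <= 0))
    return("distance thresholds must be finite and > 0")
  a1 <- object@hbondAngleMin; a2 <- object@hbondAngleMax
  if (!(is.finite(a1) && is.finite(a2) && a1 > 0 && a1 < a2 && a2 < 180))
    return("angle window must satisfy 0 < min < max < 180")
  TRUE
})

#' Construct bond-classification criteria
#'
#' @param hbondMaxDist maximum donor--acceptor distance in Angstrom.
#' @param hbondAngleMin,hbondAngleMax acceptor-angle window in degrees,
#'   inclusive at both ends.
#' @param vdwMargin van der Waals window width in Angstrom.
#' @return A [BondCriteria-class] object.
#' @examples
#' bondCriteria()
#' bondCriteria(vdwMargin = 1.0)
#' @export
bondCriteria <- function(hbondMaxDist = 3.6, hbondAngleMin = 90,
                         hbondAngleMax = 140, vdwMargin = 1.5) {
  new("BondCriteria", hbondMaxDist = hbondMaxDist,
      hbondAngleMin = hbondAngleMin, hbondAngleMax = hbondAngleMax,
      vdwMargin = vdwMargin)
}

#' Parsed protein structure
#'
#' A coordinate model parsed from a legacy PDB file: a flat atom table
#' with chain/residue/atom identity and record provenance (ATOM vs
#' HETATM), plus the MODRES and LINK annotation records needed by the
#' ligand rules.  Only the first MODEL of a multi-model file is
#' represented.
#'
#' @slot pdbId four-character identifier, or "" when unknown.
#' @slot atoms data.frame with columns record, serial, name, altloc,
#'   resname, chain, resno, icode, x, y, z, occupancy, element.
#' @slot modres data.frame (chain, resno, icode, resname) from MODRES.
#' @slot links data.frame of LINK atom-pair references.
#' @seealso [readPDBStructure()], [writePDBStructure()], [selectAltloc()]
#' @exportClass PDBStructure
setClass("PDBStructure",
         slots = c(pdbId = "character", atoms = "data.frame",
                   modres = "data.frame", links = "data.frame"))

setValidity("PDBStructure", function(object) {
  at <- object@atoms
  if (!all(ATOM_COLS %in% names(at)))
    return(sprintf("atoms must have columns: %s",
                   paste(ATOM_COLS, collapse = ", ")))
  if (nrow(at) == 0L) return("structure contains zero atoms")
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
    return("all coordinates must be finite")
  if (!all(at$record %in% c("ATOM", "HETATM")))
    return("record must be ATOM or HETATM")
  if (any(at$occupancy < 0 | at$occupancy > 1, na.rm = TRUE))
    return("occupancy must lie in [0, 1]")
  # one residue identity per (chain, resno, icode)
  key <- paste(at$chain, at$resno, at$icode, sep = "\r")
  ident <- paste(at$resname, at$record, sep = "\r")
  if (any(vapply(split(ident, key),
                 function(v) length(unique(v)) > 1L, logical(1))))
    return("(chain, resno, icode) must identify a unique residue")
  TRUE
})

#' Domain instance resolved on a structure
#'
#' One protein-family region (chain, inclusive author-numbered residue
#' range, family accession, match E-value) resolved onto the ATOM-record
#' residues of a parsed structure.  This is the unit between which
#' domain--domain interactions are called.
#'
#' @slot region one-row data.frame with the annotation fields.
#' @slot residueKeys character keys ("chain|resno|icode") of the resolved
#'   residues, in chain order.
#' @slot atomIdx integer row indices into the structure's atom table.
#' @seealso [attachDomains()]
#' @exportClass DomainInstance
setClass("DomainInstance",
         slots = c(region = "data.frame", residueKeys = "character",
                   atomIdx = "integer"))

setValidity("DomainInstance", function(object) {
  if (length(object@residueKeys) == 0L)
    return("a domain instance must contain at least one residue")
  if (length(object@atomIdx) == 0L)
    return("a domain instance must contain at least one atom")
  TRUE
})

#' Small-molecule ligand instance
#'
#' A HETATM residue that passed the ligand rules (not an aqueous solvent,
#' not a nucleic-acid component, not a covalently modified residue).
#' Identified by its Chemical Component Dictionary code and residue
#' identity.
#'
#' @slot hetCode three-character chemical component code.
#' @slot chain,resno,icode residue identity in the structure.
#' @slot atomIdx integer row indices into the structure's atom table.
#' @seealso [identifyLigands()]
#' @exportClass LigandInstance
setClass("LigandInstance",
         slots = c(hetCode = "character", chain = "character",
                   resno = "integer", icode = "character",
                   atomIdx = "integer"))

#' An aggregated domain--domain or domain--ligand interaction call
#'
#' Emitted when one or more bonds are detected between two molecules.
#' Carries topology (intramolecular = both partners on one chain),
#' family relation (homodomain = same accession, DDI only), the
#' individual higher-order bonds, and residue-level contact records in
#' which van der Waals bonds are stored as a per-residue-pair flag
#' rather than individual atom pairs.
#'
#' @slot kind "DDI" or "DLI".
#' @slot partnerA a [DomainInstance-class].
#' @slot partnerB a [DomainInstance-class] or [LigandInstance-class].
#' @slot topology "intramolecular" or "intermolecular".
#' @slot relation "homodomain"/"heterodomain" for DDI, NA for DLI.
#' @slot bonds data.frame of non-vdw bonds (atom pairs with distance and,
#'   for hydrogen bonds, acceptor angle).
#' @slot residueContacts data.frame of residue-pair contact records.
#' @slot nBondsByType named integer vector: covalent, electrostatic,
#'   hydrogen counts plus the number of residue pairs with a van der
#'   Waals flag.
#' @seealso [callInteractions()], [aggregateResidueContacts()]
#' @exportClass Interaction
setClass("Interaction",
         slots = c(kind = "character", partnerA = "DomainInstance",
                   partnerB = "ANY", topology = "character",
                   relation = "character", bonds = "data.frame",
                   residueContacts = "data.frame",
                   nBondsByType = "integer"))

setValidity("Interaction", function(object) {
  if (!object@kind %in% c("DDI", "DLI")) return("kind must be DDI or DLI")
  if (!object@topology %in% c("intramolecular", "intermolecular"))
    return("topology must be intra- or intermolecular")
  if (nrow(object@residueContacts) == 0L)
    return("an interaction requires at least one residue contact")
  if (object@kind == "DDI" &&
      !object@relation %in% c("homodomain", "heterodomain"))
    return("DDI relation must be homodomain or heterodomain")
  TRUE
})
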